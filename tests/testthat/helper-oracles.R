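# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# OLS by explicit normal equations: solve(X'X) X'y, coefficient p-values
# from the classical t statistics.
oracle_ols <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- drop(XtXi %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  tt <- beta / se
  list(beta = beta, p = 2 * pt(abs(tt), df, lower.tail = FALSE),
       resid_var = s2)
}

# Two-sided signed-rank p by exhaustive sign-flip enumeration (n <= ~16).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Ws <- signs %*% r
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# One-sided enrichment p by direct hypergeometric summation.
oracle_hyper <- function(k, K, N, nb) {
  kk <- k:min(K, nb)
  sum(choose(K, kk) * choose(N - K, nb - kk)) / choose(N, nb)
}

# Weighted inverse-regression age by brute-force grid search.
oracle_grid_age <- function(y, intercept, slope, w, lo = -200, hi = 400,
                            step = 0.001) {
  grid <- seq(lo, hi, by = step)
  obj <- vapply(grid, function(a) sum(w * (y - intercept - slope * a)^2),
                numeric(1))
  grid[which.min(obj)]
}

# Small fixture: a reference dataset most tests can share.
default_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synth_reference(n_samples = 120, n_genes = 500,
                                n_age_genes = 50, n_housekeeping = 50,
                                noise_sd = 0.5, seed = 20100929)
    }
    cache
  }
})

tmp_write <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
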