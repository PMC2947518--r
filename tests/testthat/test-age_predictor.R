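# hand-built one-gene predictor used in several blocks
toy_model <- function(aggregation = "weighted_ls",
                      genes = data.frame(gene_id = "g1", b0 = 2, b1 = 0.05,
                                         b2 = 0, b3 = 0, p1 = 1e-6, p2 = 1,
                                         p3 = 1, resid_var = 1, n = 30)) {
  structure(list(genes = genes, alpha_age = 0.005, alpha_gender = 0.05,
                 aggregation = aggregation, reference_label = "toy",
                 n_fitted = nrow(genes), n_gender_neutral = nrow(genes),
                 n_selected = nrow(genes)),
            class = "age_predictor")
}

test_that("a single gene is inverted exactly by both aggregations", {
  expect_equal(predict_age(toy_model("weighted_ls"), c(g1 = 5), "female"), 60)
  expect_equal(predict_age(toy_model("median_inversion"), c(g1 = 5), "female"), 60)
})

test_that("noiseless model-generated samples are recovered exactly", {
  set.seed(3)
  G <- 25
  genes <- data.frame(gene_id = sprintf("g%02d", 1:G),
                      b0 = runif(G, 4, 10),
                      b1 = sample(c(-1, 1), G, TRUE) * runif(G, 0.01, 0.05),
                      b2 = rnorm(G, sd = 0.01), b3 = rnorm(G, sd = 0.001),
                      p1 = 1e-6, p2 = 1, p3 = 1,
                      resid_var = runif(G, 0.05, 0.5), n = 100)
  for (agg in c("weighted_ls", "median_inversion")) {
    m <- toy_model(agg, genes)
    for (sex in c("female", "male")) {
      S <- as.numeric(sex == "male")
      y <- genes$b0 + genes$b2 * S + (genes$b1 + genes$b3 * S) * 70
      names(y) <- genes$gene_id
      expect_equal(predict_age(m, y, sex), 70, tolerance = 1e-9)
    }
  }
})

test_that("weighted_ls prediction equals a grid-search oracle", {
  set.seed(8)
  for (rep in 1:5) {
    G <- 20
    genes <- data.frame(gene_id = sprintf("g%02d", 1:G),
                        b0 = runif(G, 4, 10),
                        b1 = sample(c(-1, 1), G, TRUE) * runif(G, 0.01, 0.05),
                        b2 = rnorm(G, sd = 0.1), b3 = rnorm(G, sd = 0.005),
                        p1 = 1e-6, p2 = 1, p3 = 1,
                        resid_var = runif(G, 0.05, 0.5), n = 100)
    m <- toy_model("weighted_ls", genes)
    a <- runif(1, 30, 90)
    y <- genes$b0 + genes$b1 * a + rnorm(G, sd = 0.5)
    names(y) <- genes$gene_id
    got <- predict_age(m, y, "female")
    want <- oracle_grid_age(y, genes$b0, genes$b1, 1 / pmax(genes$resid_var, 1e-8))
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("training recovers planted age genes and rejects null data", {
  ref <- default_reference()
  m <- train_predictor(ref$expr, ref$samples)
  recovered <- mean(ref$truth$age_gene_ids %in% m$genes$gene_id)
  expect_gte(recovered, 0.9)
  # near-1 threshold keeps nearly every sex-neutral gene
  loose <- train_predictor(ref$expr, ref$samples, alpha_age = 0.999)
  expect_gte(loose$n_selected / loose$n_gender_neutral, 0.95)
  # all-null data at a tiny threshold cannot train
  null <- synth_reference(n_samples = 60, n_genes = 200, n_age_genes = 0,
                          n_housekeeping = 20, seed = 77)
  expect_error(train_predictor(null$expr, null$samples, alpha_age = 1e-6),
               "alpha_age")
})

test_that("harmonize restricts, averages multi-mapped probesets, errors on empty map", {
  genes <- data.frame(gene_id = c("a1", "a2"), b0 = c(2, 3),
                      b1 = c(0.05, -0.02), b2 = 0, b3 = 0,
                      p1 = 1e-6, p2 = 1, p3 = 1, resid_var = 1, n = 30)
  m <- toy_model(genes = genes)
  target <- matrix(c(4, 6, 1, 2, 8, 10, 3, 9), nrow = 4,
                   dimnames = list(c("b1", "b2", "b3", "b4"), c("s1", "s2")))
  # a1 maps to two probesets -> averaged; a2 to one
  map <- probeset_map(c("a1", "a1", "a2"), c("b1", "b2", "b3"))
  h <- harmonize(map, m, target)
  expect_equal(rownames(h$target), c("a1", "a2"))
  expect_equal(unname(h$target["a1", ]), c(5, 9))       # mean of 4,6 and 8,10
  expect_equal(unname(h$target["a2", ]), c(1, 3))
  expect_equal(h$model$genes$gene_id, c("a1", "a2"))
  # dropping a gene halves the model
  h2 <- harmonize(probeset_map("a2", "b3"), m, target)
  expect_equal(h2$model$genes$gene_id, "a2")
  expect_error(harmonize(probeset_map("zz", "b1"), m, target), "no model gene")
})

test_that("housekeeping offset estimation recovers constant shifts robustly", {
  set.seed(12)
  ref <- matrix(rnorm(50, 8), nrow = 5,
                dimnames = list(paste0("hk", 1:5), paste0("s", 1:10)))
  expect_equal(estimate_offset(ref, ref - 1.7, paste0("hk", 1:5))$offset, 1.7,
               tolerance = 1e-12)
  expect_equal(estimate_offset(ref, ref, paste0("hk", 1:5))$offset, 0)
  # median is robust to one outlying housekeeping gene
  target <- ref - c(0.9, 1.0, 1.1, 1.2, 5.0)
  expect_equal(estimate_offset(ref, target, paste0("hk", 1:5))$offset, 1.1)
  expect_error(estimate_offset(ref, ref, "absent"), "housekeeping")
})

test_that("apply_offset is an exact inverse and calibration reaches a fixed point", {
  set.seed(13)
  m <- matrix(rnorm(40, 7), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expect_equal(apply_offset(m, 0), m)
  expect_equal(apply_offset(apply_offset(m, 2.3), -2.3), m)
  hk <- paste0("g", 1:4)
  target <- m - 1.3
  off <- estimate_offset(m, target, hk)
  recal <- estimate_offset(m, apply_offset(target, off), hk)
  expect_equal(recal$offset, 0, tolerance = 1e-12)
})

test_that("predictions are invariant to any constant dataset offset after calibration", {
  ref <- default_reference()
  m <- train_predictor(ref$expr, ref$samples)
  coh <- synth_cohort(ref$truth, n_control = 10, n_case = 0, seed = 21)
  hk <- ref$truth$housekeeping_ids
  off0 <- estimate_offset(ref$expr, coh$expr, hk)
  base <- predict(m, apply_offset(coh$expr, off0), coh$samples)
  for (c_off in c(-5, -3, 0.5, 1.7, 5)) {
    shifted <- coh$expr + c_off
    off <- estimate_offset(ref$expr, shifted, hk)
    # the injected constant is recovered exactly on top of the (stochastic)
    # baseline difference between the two noisy datasets
    expect_equal(off$offset - off0$offset, -c_off, tolerance = 1e-9)
    expect_equal(predict(m, apply_offset(shifted, off), coh$samples),
                 base, tolerance = 1e-9)
  }
})

test_that("increasing expression increases weighted_ls age under positive slopes", {
  set.seed(14)
  G <- 10
  genes <- data.frame(gene_id = sprintf("g%02d", 1:G), b0 = runif(G, 4, 10),
                      b1 = runif(G, 0.01, 0.05), b2 = 0, b3 = 0,
                      p1 = 1e-6, p2 = 1, p3 = 1, resid_var = runif(G, 0.1, 1),
                      n = 50)
  m <- toy_model("weighted_ls", genes)
  y <- genes$b0 + genes$b1 * 60
  names(y) <- genes$gene_id
  a0 <- predict_age(m, y, "female")
  a1 <- predict_age(m, y + 0.2, "female")
  expect_gt(a1, a0)
})

test_that("predictor JSON serialization round-trips", {
  ref <- default_reference()
  m <- train_predictor(ref$expr, ref$samples)
  f <- tempfile(fileext = ".json")
  write_predictor(m, f)
  back <- read_predictor(f)
  expect_equal(back$genes$b1, m$genes$b1, tolerance = 1e-12)
  expect_equal(back$aggregation, m$aggregation)
  y <- ref$expr[, 1]
  expect_equal(predict_age(back, y, ref$samples$sex[1]),
               predict_age(m, y, ref$samples$sex[1]), tolerance = 1e-9)
})
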