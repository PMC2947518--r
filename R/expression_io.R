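#' Read a log2 expression matrix from a tab-delimited file
#'
#' The expected layout is the one GEO series-matrix exports reduce to after
#' preprocessing: first row holds sample IDs (the top-left corner cell is
#' ignored), first column holds gene/probeset IDs, and the body holds decimal
#' log2 expression values.
#'
#' @param path Path to a tab-delimited text file.
#' @return A numeric matrix (genes x samples) with unique rownames (gene IDs)
#'   and colnames (sample IDs), all values finite. Row and column order are
#'   preserved from the file.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("expression matrix file must have a gene-ID column plus >= 1 sample column: ", path)
  }
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicated gene ID(s) in ", path, ": ",
         paste(utils::head(dup_g, 5L), collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(utils::head(dup_s, 5L), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite cell '%s' at gene '%s', sample '%s' in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write a log2 expression matrix to a tab-delimited file
#'
#' @param m Numeric matrix with rownames (gene IDs) and colnames (sample IDs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m),
            !is.null(rownames(m)), !is.null(colnames(m)))
  out <- data.frame(gene_id = rownames(m),
                    format(m, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a tab-delimited file with header columns `sample_id`, `age`,
#' `sex` and `group`. Sex tokens `F`/`female` and `M`/`male` are accepted
#' case-insensitively and normalised to `"female"` / `"male"`.
#'
#' @param path Path to a tab-delimited text file.
#' @return A data.frame with columns `sample_id` (character), `age` (numeric
#'   years, in \[0, 150\]), `sex` (`"female"` or `"male"`) and `group`
#'   (character label, e.g. control/AD).
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "group")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop("sample table ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         " (found: ", paste(colnames(tab), collapse = ", "), ")")
  }
  age <- suppressWarnings(as.numeric(tab$age))
  bad <- which(is.na(age) | age < 0 | age > 150)
  if (length(bad)) {
    stop("invalid age '", tab$age[bad[1L]], "' for sample '",
         tab$sample_id[bad[1L]], "' (must be a number in [0, 150])")
  }
  sex <- normalize_sex(tab$sex, tab$sample_id)
  dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(dup)) {
    stop("duplicated sample ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  data.frame(sample_id = tab$sample_id, age = age, sex = sex,
             group = tab$group, stringsAsFactors = FALSE)
}

normalize_sex <- function(tokens, ids = NULL) {
  low <- tolower(trimws(tokens))
  out <- ifelse(low %in% c("f", "female"), "female",
                ifelse(low %in% c("m", "male"), "male", NA_character_))
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    who <- if (is.null(ids)) "" else paste0(" (sample '", ids[i], "')")
    stop("unknown sex token '", tokens[i], "'", who,
         "; expected F/female or M/male")
  }
  out
}

#' Write a sample metadata table
#'
#' @param samples Data.frame as returned by [read_sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "age", "sex", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Affymetrix-style best-match probeset table
#'
#' Reads a comma-separated comparison spreadsheet and extracts the pairs
#' relating probeset IDs on two array generations. Rows with an empty ID on
#' either side are dropped and duplicate pairs collapsed; match-quality
#' scores, if present, are ignored.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_a Name of the column holding IDs on the first platform
#'   (the platform of a trained model).
#' @param col_b Name of the column holding IDs on the second platform
#'   (the platform of a target dataset).
#' @return A data.frame of class `probeset_map` with character columns
#'   `ref_id` and `target_id`, one row per unique pair.
#' @export
read_best_match_table <- function(path, col_a, col_b) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  miss <- setdiff(c(col_a, col_b), colnames(tab))
  if (length(miss)) {
    stop("best-match table ", path, " lacks column(s) ",
         paste(sQuote(miss), collapse = ", "),
         "; available columns: ", paste(colnames(tab), collapse = ", "))
  }
  a <- trimws(tab[[col_a]])
  b <- trimws(tab[[col_b]])
  keep <- nzchar(a) & nzchar(b)
  map <- unique(data.frame(ref_id = a[keep], target_id = b[keep],
                           stringsAsFactors = FALSE))
  rownames(map) <- NULL
  class(map) <- c("probeset_map", "data.frame")
  map
}

#' Build a probeset map from two ID vectors
#'
#' Convenience constructor with the same semantics as
#' [read_best_match_table()] (empty pairs dropped, duplicates collapsed).
#'
#' @param ref_id,target_id Character vectors of equal length.
#' @return A `probeset_map` data.frame.
#' @export
probeset_map <- function(ref_id, target_id) {
  stopifnot(length(ref_id) == length(target_id))
  keep <- nzchar(ref_id) & nzchar(target_id)
  map <- unique(data.frame(ref_id = as.character(ref_id)[keep],
                           target_id = as.character(target_id)[keep],
                           stringsAsFactors = FALSE))
  rownames(map) <- NULL
  class(map) <- c("probeset_map", "data.frame")
  map
}

#' Read a gene-ID list (one ID per line)
#'
#' Blank lines and lines starting with `#` are ignored; duplicates are
#' collapsed. Intended for e.g. a housekeeping-gene list used in
#' cross-dataset calibration. The identifier space (probeset vs symbol) is
#' the caller's responsibility.
#'
#' @param path Path to a plain text file.
#' @return Character vector of unique IDs; a warning is emitted when empty.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (!length(ids)) warning("gene list ", path, " is empty")
  ids
}

# internal: check an expression matrix + sample table pair is consistent and
# return the matrix with columns ordered as samples$sample_id
align_expr_samples <- function(expr, samples) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  miss <- setdiff(samples$sample_id, colnames(expr))
  if (length(miss)) {
    stop("sample(s) absent from expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  expr[, samples$sample_id, drop = FALSE]
}
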