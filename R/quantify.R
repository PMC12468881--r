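#' Read a count matrix / sample-group table from TSV
#'
#' The count TSV has features as rows, a first column named `feature` (or
#' unnamed) and one column per sample. The group TSV has two columns,
#' `sample` and `group` (tissue or stage label).
#'
#' @param file path to a TSV file.
#' @return a tibble.
#' @export
read_counts <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE)
  names(out)[1] <- "feature"
  assert_counts(out)
  out
}

#' @rdname read_counts
#' @export
read_groups <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE)
  names(out)[1:2] <- c("sample", "group")
  out
}

#' Filter lowly expressed features
#'
#' A feature is kept when there exists at least one group (tissue) in which
#' strictly more than `min_reads` raw counts are observed in at least
#' `min_samples` of that group's samples. Note a group with fewer than
#' `min_samples` samples can never qualify a feature on its own.
#'
#' @param counts count tibble (`feature` column plus one column per sample).
#' @param groups data frame with columns `sample`, `group`.
#' @param min_reads count threshold; "more than" is strict (default 10, so a
#'   qualifying sample needs >= 11 reads).
#' @param min_samples minimum number of qualifying samples within one group
#'   (default 3).
#' @return the filtered count tibble (rows kept in input order).
#' @export
filter_expression <- function(counts, groups, min_reads = 10, min_samples = 3) {
  assert_counts(counts)
  assert_groups(counts, groups)
  stopifnot(min_reads >= 1, min_samples >= 1)
  m <- counts_matrix(counts)
  grp <- stats::setNames(groups$group, groups$sample)[colnames(m)]
  keep <- rep(FALSE, nrow(m))
  for (g in unique(grp)) {
    sub <- m[, grp == g, drop = FALSE]
    keep <- keep | rowSums(sub > min_reads) >= min_samples
  }
  counts[keep, ]
}

#' Counts-per-million normalization
#'
#' @inheritParams filter_expression
#' @return expression tibble of the same shape with attribute `unit = "CPM"`;
#'   each sample column sums to 1e6 when the sample has any reads.
#' @export
cpm_normalize <- function(counts) {
  assert_counts(counts)
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("samples with zero library size: ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  matrix_to_tbl(sweep(m, 2, lib, "/") * 1e6, unit = "CPM")
}

#' Median-of-ratios size factors
#'
#' The per-sample size factor is the median, over features with strictly
#' positive counts in every sample, of the ratio of the sample's count to the
#' feature's geometric mean across samples. Factors are rescaled so their
#' geometric mean is 1 (identifiability convention).
#'
#' @inheritParams filter_expression
#' @return tibble with columns `sample`, `size_factor`.
#' @export
mor_size_factors <- function(counts) {
  assert_counts(counts)
  m <- counts_matrix(counts)
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop("no feature has positive counts in all samples; ",
         "add a pseudocount or use CPM normalization", call. = FALSE)
  }
  mu <- m[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(mu)))
  sf <- apply(mu / geo, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))  # geometric mean of factors = 1
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Median-of-ratios normalization
#'
#' Divides each sample's counts by its [mor_size_factors()] factor.
#'
#' @inheritParams filter_expression
#' @return expression tibble with attribute `unit = "MoR"`.
#' @export
mor_normalize <- function(counts) {
  sf <- mor_size_factors(counts)
  m <- counts_matrix(counts)
  matrix_to_tbl(sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample)], "/"),
                unit = "MoR")
}

#' Per-feature per-group mean expression
#'
#' @param expr normalized expression tibble (`feature` column plus samples),
#'   e.g. from [cpm_normalize()].
#' @inheritParams filter_expression
#' @return tibble with columns `feature`, `group`, `mean_expr`; groups in
#'   lexicographic order, features in input order.
#' @export
tissue_means <- function(expr, groups) {
  assert_counts(expr, "expr")
  assert_groups(expr, groups)
  m <- counts_matrix(expr)
  if (nrow(m) == 0) {
    return(tibble::tibble(feature = character(), group = character(),
                          mean_expr = double()))
  }
  grp <- stats::setNames(groups$group, groups$sample)[colnames(m)]
  glev <- sort(unique(grp))
  means <- vapply(glev, function(g) rowMeans(m[, grp == g, drop = FALSE]),
                  numeric(nrow(m)))
  if (nrow(m) == 1) means <- matrix(means, nrow = 1, dimnames = list(rownames(m), glev))
  tibble::tibble(
    feature = rep(rownames(m), times = length(glev)),
    group = rep(glev, each = nrow(m)),
    mean_expr = as.vector(means)
  ) |>
    dplyr::arrange(match(.data$feature, rownames(m)), .data$group)
}
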