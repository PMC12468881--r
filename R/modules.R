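#' Module eigengene
#'
#' The eigengene summarizing a co-expression module is the first right
#' singular vector of the module's feature-standardized expression matrix
#' (each feature centred to mean 0 and scaled to sd 1 across samples). Its
#' sign is fixed so that the mean of the per-feature correlations with the
#' eigengene is non-negative. Zero-variance features are excluded with a
#' warning.
#'
#' @param expr expression tibble (`feature` column plus sample columns)
#'   restricted to one module's features; >= 2 features and >= 3 samples.
#' @return tibble with columns `sample`, `eigengene` (unit-norm vector).
#' @export
module_eigengene <- function(expr) {
  assert_expr(expr)
  m <- counts_matrix(expr)
  if (ncol(m) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) excluded from eigengene",
            call. = FALSE)
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least 2 features with variance", call. = FALSE)
  z <- t(scale(t(m)))
  sv <- svd(z, nu = 0, nv = 1)
  e <- drop(sv$v)
  if (mean(stats::cor(t(z), e)) < 0) e <- -e
  tibble::tibble(sample = colnames(m), eigengene = e)
}

#' Module membership and gene significance
#'
#' MM is the Pearson correlation of each feature's expression profile with
#' the module eigengene; GS is the Pearson correlation with a trait
#' indicator (conventionally 1 for samples of the tissue of interest, 0
#' otherwise). Zero-variance profiles or a constant trait give NA.
#'
#' @param expr expression tibble for the module's features.
#' @param eigengene tibble from [module_eigengene()] (or a numeric vector in
#'   sample order).
#' @param trait numeric per-sample trait indicator, in the same sample order
#'   as `expr`'s columns.
#' @return tibble of class `module_stats` with columns `feature`, `MM`, `GS`.
#' @export
module_membership_gs <- function(expr, eigengene, trait) {
  assert_expr(expr)
  m <- counts_matrix(expr)
  e <- if (is.data.frame(eigengene)) {
    eigengene$eigengene[match(colnames(m), eigengene$sample)]
  } else {
    as.numeric(eigengene)
  }
  stopifnot(length(e) == ncol(m), length(trait) == ncol(m), ncol(m) >= 3)
  safe_cor <- function(x, y) {
    if (stats::var(x) == 0 || stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  }
  out <- tibble::tibble(
    feature = rownames(m),
    MM = unname(apply(m, 1, safe_cor, y = e)),
    GS = unname(apply(m, 1, safe_cor, y = as.numeric(trait)))
  )
  class(out) <- c("module_stats", class(out))
  out
}

#' Flag hub features of a module
#'
#' A hub satisfies |MM| > `mm_min` and |GS| > `gs_min`, both strict
#' (defaults 0.8 and 0.2). Missing MM or GS means not a hub.
#'
#' @param stats tibble with columns `feature`, `MM`, `GS` (e.g. from
#'   [module_membership_gs()]).
#' @param mm_min,gs_min strict absolute thresholds.
#' @return `stats` with an added logical `is_hub` column.
#' @export
select_hubs <- function(stats, mm_min = 0.8, gs_min = 0.2) {
  stopifnot(all(c("feature", "MM", "GS") %in% names(stats)))
  dplyr::mutate(
    tibble::as_tibble(stats),
    is_hub = !is.na(.data$MM) & !is.na(.data$GS) &
      abs(.data$MM) > mm_min & abs(.data$GS) > gs_min
  )
}
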