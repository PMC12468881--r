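#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; atlas reports use conventional
#' half-up rounding (e.g. percentages to one decimal), so this helper exists.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) is 0.2
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Shared argument checks ------------------------------------------------------

assert_counts <- function(counts, arg = "counts", non_negative = TRUE) {
  if (!is.data.frame(counts)) {
    stop("`", arg, "` must be a data frame with a `feature` column", call. = FALSE)
  }
  if (!"feature" %in% names(counts)) {
    stop("`", arg, "` must have a `feature` column", call. = FALSE)
  }
  if (anyDuplicated(counts$feature)) {
    stop("feature ids in `", arg, "` must be unique", call. = FALSE)
  }
  if (non_negative) {
    vals <- as.matrix(counts[setdiff(names(counts), "feature")])
    if (length(vals) && any(vals < 0, na.rm = TRUE)) {
      stop("`", arg, "` contains negative values", call. = FALSE)
    }
  }
  invisible(counts)
}

# expression profiles may be on any scale (e.g. centred residuals)
assert_expr <- function(expr, arg = "expr") {
  assert_counts(expr, arg, non_negative = FALSE)
}

assert_groups <- function(counts, groups) {
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    stop("`groups` must be a data frame with columns `sample` and `group`", call. = FALSE)
  }
  samples <- setdiff(names(counts), "feature")
  missing <- setdiff(samples, groups$sample)
  if (length(missing)) {
    stop("samples without a group assignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(groups)
}

# counts tibble -> numeric matrix (features x samples)
counts_matrix <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "feature")])
  rownames(m) <- counts$feature
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, unit = NULL) {
  out <- tibble::as_tibble(m, rownames = "feature")
  if (!is.null(unit)) attr(out, "unit") <- unit
  out
}
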