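#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p sorted ascending,
#' `p_adj[i] = min(k >= i) p[k] * m / k`, capped at 1 and returned in the
#' input order (delegated to [stats::p.adjust()]).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed features
#'
#' A record is differentially expressed when its BH-adjusted p-value is
#' strictly below `fdr` (default 0.05) and its absolute log2 fold change is
#' at least `lfc` (default 1, inclusive). If the table has no `p_adj`
#' column, one is computed from `p` with [bh_adjust()] (per contrast when a
#' `contrast` column is present).
#'
#' @param de tibble with columns `feature`, `log2fc` and `p_adj` (or raw
#'   `p`); optionally `contrast`.
#' @param fdr adjusted-p threshold, strict.
#' @param lfc absolute log2 fold-change threshold, inclusive.
#' @return `de` with columns `p_adj` and logical `is_de` added.
#' @export
select_de <- function(de, fdr = 0.05, lfc = 1) {
  de <- tibble::as_tibble(de)
  stopifnot(all(c("feature", "log2fc") %in% names(de)))
  if (!"p_adj" %in% names(de)) {
    if (!"p" %in% names(de)) stop("need a `p_adj` or `p` column", call. = FALSE)
    de <- if ("contrast" %in% names(de)) {
      de |>
        dplyr::group_by(.data$contrast) |>
        dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
        dplyr::ungroup()
    } else {
      dplyr::mutate(de, p_adj = bh_adjust(.data$p))
    }
  }
  dplyr::mutate(de, is_de = .data$p_adj < fdr & abs(.data$log2fc) >= lfc)
}
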