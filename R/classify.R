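#' Atlas decision thresholds
#'
#' One object collecting every decision threshold used across the pipeline,
#' with the study defaults: housekeeping CV < 1; tissue-specific top-25%
#' rank, > 50% share, >= 3x any other tissue; DE FDR < 0.05 and |log2FC| >= 1;
#' cis window +/- 100 kb with Pearson r > 0.6; hub |MM| > 0.8 and |GS| > 0.2;
#' miRNA interaction score > 140 and energy < -20 kcal/mol.
#'
#' @param ... named overrides of any default; unknown names are rejected.
#' @return a named list of class `atlas_thresholds`.
#' @export
atlas_thresholds <- function(...) {
  thr <- list(
    cv_max = 1, rank_top = 0.25, share_min = 0.5, ratio_min = 3,
    de_fdr = 0.05, de_lfc = 1,
    cis_window = 1e5, cis_r = 0.6,
    mm_min = 0.8, gs_min = 0.2,
    mirna_score = 140, mirna_energy = -20
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(thr))
  if (length(unknown)) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  thr[names(over)] <- over
  structure(thr, class = "atlas_thresholds")
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' A zero mean gives `Inf`: such a feature can never be called housekeeping.
#'
#' @param values numeric vector of per-tissue means (length >= 2).
#' @return non-negative scalar (possibly `Inf`).
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) return(Inf)
  stats::sd(values) / m
}

#' Cross-tissue expression summary
#'
#' Computes, per feature, the per-tissue mean expression together with the
#' derived statistics the housekeeping / tissue-specific classifiers use:
#' the overall mean (arithmetic mean of tissue means), the coefficient of
#' variation across tissue means, each tissue's share of the feature's total
#' expression, and the within-tissue quantile rank
#' `(number of features with strictly smaller mean) / (n - 1)` (ties share
#' the lower rank; 1 when there is a single feature).
#'
#' @inheritParams tissue_means
#' @return a tibble of class `tissue_summary`, one row per feature x group:
#'   `feature`, `group`, `mean_expr`, `share`, `rank_q`, plus the per-feature
#'   `overall_mean` and `cv` repeated along rows.
#' @export
tissue_summary <- function(expr, groups) {
  tm <- tissue_means(expr, groups)
  n_feat <- dplyr::n_distinct(tm$feature)
  out <- tm |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(
      overall_mean = mean(.data$mean_expr),
      cv = if (dplyr::n() >= 2 && mean(.data$mean_expr) > 0) {
        stats::sd(.data$mean_expr) / mean(.data$mean_expr)
      } else if (dplyr::n() >= 2) Inf else NA_real_,
      share = if (sum(.data$mean_expr) > 0) {
        .data$mean_expr / sum(.data$mean_expr)
      } else rep(0, dplyr::n())
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      rank_q = if (n_feat > 1) {
        (rank(.data$mean_expr, ties.method = "min") - 1) / (n_feat - 1)
      } else 1
    ) |>
    dplyr::ungroup()
  class(out) <- c("tissue_summary", class(out))
  out
}

#' Housekeeping classification
#'
#' A feature is housekeeping when (i) its overall mean expression strictly
#' exceeds the median of all features' overall means and (ii) its
#' cross-tissue CV is strictly below `thr$cv_max` (default 1). The median is
#' taken over exactly the feature set in `ts`, so restricting the input to
#' lncRNAs or pooling lncRNAs with mRNAs is a data-selection choice.
#'
#' @param ts a `tissue_summary`.
#' @param thr an [atlas_thresholds()] object.
#' @return sorted character vector of housekeeping feature ids.
#' @export
classify_housekeeping <- function(ts, thr = atlas_thresholds()) {
  if (dplyr::n_distinct(ts$group) < 2) {
    stop("housekeeping CV needs at least two tissues", call. = FALSE)
  }
  per <- dplyr::distinct(ts, .data$feature, .data$overall_mean, .data$cv)
  med <- stats::median(per$overall_mean)
  sort(per$feature[per$overall_mean > med & per$cv < thr$cv_max])
}

#' Tissue-specific classification
#'
#' A feature is specific to tissue T when (i) its mean expression in T ranks
#' in the top 25% of all features within T (`rank_q >= 1 - thr$rank_top`),
#' (ii) T accounts for strictly more than half of the feature's total
#' expression, and (iii) the mean in T is at least `thr$ratio_min` (default
#' 3) times the maximum mean over the other tissues ("at least" is
#' inclusive; when all other tissues are zero and T is positive, the ratio
#' clause passes vacuously). Clause (ii) can hold for at most one tissue, so
#' the assignment is unique.
#'
#' @inheritParams classify_housekeeping
#' @return tibble with columns `feature`, `tissue`, ordered by feature.
#' @export
classify_tissue_specific <- function(ts, thr = atlas_thresholds()) {
  if (dplyr::n_distinct(ts$group) < 2) {
    stop("tissue specificity needs at least two tissues", call. = FALSE)
  }
  hits <- ts |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(max_other = max_other(.data$mean_expr)) |>
    dplyr::ungroup() |>
    dplyr::filter(
      .data$rank_q >= 1 - thr$rank_top,
      .data$share > thr$share_min,
      .data$mean_expr > 0,
      .data$max_other == 0 | .data$mean_expr >= thr$ratio_min * .data$max_other
    )
  stopifnot(!anyDuplicated(hits$feature))  # share > 1/2 is unique by construction
  tibble::tibble(feature = hits$feature, tissue = hits$group) |>
    dplyr::arrange(.data$feature)
}

# max over the other entries, elementwise
max_other <- function(x) {
  if (length(x) == 1) return(rep(0, 1))
  vapply(seq_along(x), function(i) max(x[-i]), numeric(1))
}

#' Classify every feature as housekeeping, tissue-specific or neither
#'
#' Composes [tissue_summary()], [classify_housekeeping()] and
#' [classify_tissue_specific()] over a normalized expression matrix. All
#' criteria are scale-free, so the labels are invariant under a global
#' positive rescaling of the matrix. A feature that satisfies both rule sets
#' is labelled tissue-specific (a > 50% single-tissue share contradicts the
#' housekeeping notion); features with zero overall mean are `neither`.
#'
#' @inheritParams tissue_means
#' @param thr an [atlas_thresholds()] object.
#' @return a tibble of class `lnc_classification`, one row per feature:
#'   `feature`, `label` (`housekeeping` / `tissue_specific` / `neither`),
#'   `tissue` (NA unless tissue-specific) and the evidence columns
#'   `overall_mean`, `cv`, `best_share`, `best_ratio`, `rank_q` (at the
#'   best-share tissue).
#' @export
classify_features <- function(expr, groups, thr = atlas_thresholds()) {
  if (nrow(expr) == 0) {
    out <- tibble::tibble(feature = character(), label = character(),
                          tissue = character(), overall_mean = double(),
                          cv = double(), best_share = double(),
                          best_ratio = double(), rank_q = double())
    class(out) <- c("lnc_classification", class(out))
    return(out)
  }
  ts <- tissue_summary(expr, groups)
  hk <- classify_housekeeping(ts, thr)
  tsp <- classify_tissue_specific(ts, thr)

  evidence <- ts |>
    dplyr::group_by(.data$feature) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$group, .by_group = TRUE) |>
    dplyr::summarise(
      overall_mean = .data$overall_mean[1],
      cv = .data$cv[1],
      best_share = .data$share[1],
      best_ratio = ratio_to_others(.data$mean_expr),
      rank_q = .data$rank_q[1],
      .groups = "drop"
    )
  out <- evidence |>
    dplyr::left_join(tsp, by = "feature") |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$overall_mean == 0 ~ "neither",
        !is.na(.data$tissue) ~ "tissue_specific",
        .data$feature %in% hk ~ "housekeeping",
        TRUE ~ "neither"
      )
    ) |>
    dplyr::select("feature", "label", "tissue", "overall_mean", "cv",
                  "best_share", "best_ratio", "rank_q") |>
    dplyr::arrange(.data$feature)
  class(out) <- c("lnc_classification", class(out))
  out
}

# best tissue mean over the max of the others (Inf when others all zero)
ratio_to_others <- function(means) {
  i <- which.max(means)
  others <- means[-i]
  if (!length(others) || max(others) == 0) {
    if (means[i] > 0) Inf else NA_real_
  } else {
    means[i] / max(others)
  }
}

#' @export
tidy.lnc_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lnc_classification")
  out
}

#' @export
glance.lnc_classification <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_housekeeping = sum(x$label == "housekeeping"),
    n_tissue_specific = sum(x$label == "tissue_specific"),
    n_neither = sum(x$label == "neither")
  )
}

#' @export
autoplot.lnc_classification <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$cv), .data$overall_mean > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overall_mean, y = .data$cv,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "overall mean expression (log scale)",
                  y = "cross-tissue CV", colour = NULL,
                  title = "Housekeeping / tissue-specific classification")
}
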