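#' Per-stage mean expression
#'
#' @param expr expression tibble (CPM recommended).
#' @param stages data frame with columns `sample`, `group` (stage label,
#'   e.g. AF1..AF5).
#' @return tibble `feature` x stage columns (wide), stages in lexicographic
#'   order.
#' @export
stage_means <- function(expr, stages) {
  tissue_means(expr, stages) |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_expr")
}

#' Stage-by-stage correlation matrix
#'
#' Correlation (Spearman by default) between per-stage mean expression
#' profiles over the shared features. A constant profile yields NA against
#' the other stages; the diagonal is 1 by convention.
#'
#' @inheritParams stage_means
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric stage x stage correlation matrix.
#' @export
stage_correlation_matrix <- function(expr, stages, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  sm <- stage_means(expr, stages)
  m <- as.matrix(sm[, -1])
  if (ncol(m) < 2) stop("need at least two stages", call. = FALSE)
  if (nrow(m) < 3) stop("need at least three shared features", call. = FALSE)
  r <- suppressWarnings(stats::cor(m, method = method))
  diag(r) <- 1
  r
}

#' Match features to temporal template profiles
#'
#' Each feature's stage means are standardized (mean 0, sd 1 across stages)
#' and correlated (Pearson) with every template profile; the feature is
#' assigned to the best-correlated template when that correlation is at
#' least `r_min` (default 0.7), ties going to the lowest template index.
#' Standardization makes the assignment invariant to affine transformations
#' of a feature's stage means; flat (zero-variance) features stay
#' unassigned.
#'
#' @param stage_means wide tibble from [stage_means()] (`feature` column
#'   plus one column per stage).
#' @param templates tibble with a `profile_id` column plus one column per
#'   stage (same stage columns as `stage_means`); at most 50 templates.
#' @param r_min minimum correlation for an assignment (default 0.7).
#' @return tibble with columns `feature`, `profile_id` (NA if unassigned),
#'   `match_r`.
#' @export
assign_profiles <- function(stage_means, templates, r_min = 0.7) {
  templates <- tibble::as_tibble(templates)
  stopifnot("profile_id" %in% names(templates))
  if (nrow(templates) > 50) stop("at most 50 template profiles", call. = FALSE)
  stage_cols <- setdiff(names(stage_means), "feature")
  if (!all(stage_cols %in% names(templates))) {
    stop("templates must have the same stage columns as `stage_means`", call. = FALSE)
  }
  fm <- as.matrix(stage_means[, stage_cols])
  tm <- as.matrix(templates[, stage_cols])
  purrr::map_dfr(seq_len(nrow(fm)), function(i) {
    x <- fm[i, ]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(feature = stage_means$feature[i],
                            profile_id = templates$profile_id[NA_integer_],
                            match_r = NA_real_))
    }
    z <- (x - mean(x)) / stats::sd(x)
    r <- apply(tm, 1, function(t) {
      if (stats::sd(t) == 0) NA_real_ else stats::cor(z, t)
    })
    best <- which(r == max(r, na.rm = TRUE))[1]
    assigned <- !is.na(r[best]) && r[best] >= r_min
    tibble::tibble(
      feature = stage_means$feature[i],
      profile_id = if (assigned) templates$profile_id[best] else
        templates$profile_id[NA_integer_],
      match_r = if (is.finite(suppressWarnings(max(r, na.rm = TRUE)))) max(r, na.rm = TRUE) else NA_real_
    )
  })
}

#' Select key lncRNAs
#'
#' Key lncRNAs are those that are (a) differentially expressed in at least
#' one stage contrast and (b) assigned to one of the enriched temporal
#' profiles.
#'
#' @param assignments tibble from [assign_profiles()].
#' @param de_features character vector of differentially expressed feature
#'   ids (union over contrasts).
#' @param enriched_profiles vector of enriched profile ids.
#' @return tibble with columns `feature`, `profile_id`, sorted by feature.
#' @export
select_key_lncs <- function(assignments, de_features, enriched_profiles) {
  assignments |>
    dplyr::filter(!is.na(.data$profile_id),
                  .data$profile_id %in% enriched_profiles,
                  .data$feature %in% de_features) |>
    dplyr::select("feature", "profile_id") |>
    dplyr::arrange(.data$feature)
}
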