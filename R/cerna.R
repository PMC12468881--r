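#' Filter predicted miRNA interaction edges
#'
#' Retains miRanda-style edges with binding score strictly above
#' `score_min` (default 140) and duplex energy strictly below `energy_max`
#' (default -20 kcal/mol). Edges with a missing score or energy are dropped
#' with a warning.
#'
#' @param edges tibble with columns `source`, `target`, `score`, `energy`.
#' @param score_min,energy_max strict thresholds.
#' @return the retained edge rows.
#' @export
filter_interactions <- function(edges, score_min = 140, energy_max = -20) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "score", "energy") %in% names(edges)))
  bad <- is.na(edges$score) | is.na(edges$energy)
  if (any(bad)) {
    warning(sum(bad), " edge(s) dropped: missing score or energy", call. = FALSE)
    edges <- edges[!bad, , drop = FALSE]
  }
  edges[edges$score > score_min & edges$energy < energy_max, , drop = FALSE]
}

#' Assemble ceRNA sponge-miRNA-mRNA triples
#'
#' Joins sponge (lncRNA/circRNA) to miRNA edges with miRNA to mRNA edges on
#' the shared miRNA: a triple (s, m, g) exists iff edge (s, m) and edge
#' (m, g) both exist in the (already filtered) inputs. Triples are
#' deduplicated and returned in deterministic order.
#'
#' @param sponge_mirna tibble with columns `source` (sponge id), `target`
#'   (miRNA id).
#' @param mirna_mrna tibble with columns `source` (miRNA id), `target`
#'   (mRNA id).
#' @return tibble with columns `sponge`, `mirna`, `mrna`, sorted.
#' @export
assemble_cerna <- function(sponge_mirna, mirna_mrna) {
  s <- dplyr::distinct(tibble::as_tibble(sponge_mirna),
                       sponge = .data$source, mirna = .data$target)
  g <- dplyr::distinct(tibble::as_tibble(mirna_mrna),
                       mirna = .data$source, mrna = .data$target)
  dplyr::inner_join(s, g, by = "mirna", relationship = "many-to-many") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$sponge, .data$mirna, .data$mrna)
}

#' Rank sponges by interaction score
#'
#' Aggregates each sponge's retained edge scores (maximum by default; the
#' alternative `"sum"` rewards many bindings) and returns the top `n`.
#'
#' @param edges retained edge tibble (`source`, `target`, `score`).
#' @param n number of sponges to return (default 5).
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return tibble with columns `source`, `score`, sorted descending.
#' @export
rank_sponges <- function(edges, n = 5, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "max") max else sum
  tibble::as_tibble(edges) |>
    dplyr::group_by(source = .data$source) |>
    dplyr::summarise(score = f(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$source) |>
    utils::head(n)
}
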