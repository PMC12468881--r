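#' Call positionally conserved lncRNAs from lifted coordinates
#'
#' A foreign lncRNA is positionally conserved when any of its lifted
#' fragments overlaps the span of any pig lncRNA by at least
#' `min_overlap_bp` (default 1 bp). Overlap is strand-agnostic by default
#' (set `require_strand = TRUE` to demand matching strands). Source ids
#' whose liftover failed can be passed through `unmapped` for bookkeeping;
#' they are never conserved.
#'
#' @param lifted BED-style tibble of lifted intervals (`chrom`, `start`,
#'   `end`, `name` = foreign lncRNA id, optionally `strand`); several
#'   fragments may share one name.
#' @param ann `lnc_annotation` whose lncRNA transcripts are the pig loci.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param require_strand require equal strand for an overlap to count.
#' @param unmapped character vector of foreign ids with no lifted fragment.
#' @return tibble of class `conservation_calls`, one row per source id:
#'   `source_id`, `mapped`, `n_fragments`, `overlaps` (list column of pig
#'   transcript ids), `conserved`.
#' @export
call_conserved <- function(lifted, ann, min_overlap_bp = 1,
                           require_strand = FALSE, unmapped = character()) {
  stopifnot(inherits(ann, "lnc_annotation"), min_overlap_bp >= 1)
  lifted <- tibble::as_tibble(lifted)
  if (nrow(lifted)) validate_intervals(lifted, "lifted")
  pig <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]

  frag_overlaps <- function(i) {
    p <- pig[pig$chrom == lifted$chrom[i], ]
    if (require_strand && "strand" %in% names(lifted)) {
      p <- p[p$strand == lifted$strand[i], ]
    }
    if (nrow(p) == 0) return(character())
    ov <- pmin(lifted$end[i], p$end) - pmax(lifted$start[i], p$start)
    p$transcript_id[ov >= min_overlap_bp]
  }
  hits <- purrr::map(seq_len(nrow(lifted)), frag_overlaps)

  mapped <- tibble::tibble(source_id = lifted$name, hit = hits) |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      mapped = TRUE,
      n_fragments = dplyr::n(),
      overlaps = list(sort(unique(unlist(.data$hit)))),
      .groups = "drop"
    )
  un <- tibble::tibble(
    source_id = setdiff(unmapped, mapped$source_id),
    mapped = FALSE, n_fragments = 0L,
    overlaps = list(character())
  )
  out <- dplyr::bind_rows(mapped, un) |>
    dplyr::mutate(conserved = .data$mapped & lengths(.data$overlaps) > 0) |>
    dplyr::arrange(.data$source_id)
  class(out) <- c("conservation_calls", class(out))
  out
}

#' Conservation-rate report
#'
#' Summarizes conservation calls into counts and a percentage rounded
#' half-up to one decimal, the convention used when reporting conserved
#' fractions (e.g. 1078 conserved of 13380 source lncRNAs is 8.1%).
#'
#' @param records a `conservation_calls` tibble, or NULL when passing counts
#'   directly.
#' @param n_source total number of foreign source lncRNAs (the denominator);
#'   must be >= the number of records.
#' @param n_conserved,n_mapped counts, only used when `records` is NULL
#'   (`n_mapped` defaults to `n_conserved`).
#' @return one-row tibble: `n_source`, `n_mapped`, `n_conserved`, `rate_pct`.
#' @export
conservation_report <- function(records = NULL, n_source,
                                n_conserved = NULL, n_mapped = NULL) {
  if (!is.null(records)) {
    n_mapped <- sum(records$mapped)
    n_conserved <- sum(records$conserved)
    if (n_source < nrow(records)) {
      stop("`n_source` must be at least the number of records", call. = FALSE)
    }
  } else {
    if (is.null(n_conserved)) stop("supply `records` or `n_conserved`", call. = FALSE)
    if (is.null(n_mapped)) n_mapped <- n_conserved
  }
  if (n_source <= 0) stop("`n_source` must be positive", call. = FALSE)
  if (!(n_conserved <= n_mapped && n_mapped <= n_source)) {
    stop("need n_conserved <= n_mapped <= n_source", call. = FALSE)
  }
  tibble::tibble(
    n_source = n_source, n_mapped = n_mapped, n_conserved = n_conserved,
    rate_pct = round_half_up(100 * n_conserved / n_source, 1)
  )
}
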