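#' Candidate cis-target genes within a window of each lncRNA
#'
#' A protein-coding gene is a cis candidate for a lncRNA when its span lies
#' within `window_bp` of the lncRNA span on the same chromosome, measured
#' edge to edge (overlapping spans have distance 0); strand is ignored.
#' Gene spans are the union of the gene's coding transcript spans.
#'
#' @param ann an `lnc_annotation` with lncRNA and protein-coding transcripts.
#' @param window_bp neighbourhood size in bp (default 100000, i.e. +/-100 kb).
#' @param lnc_ids optional subset of lncRNA transcript ids.
#' @return tibble with columns `lnc`, `gene`, `distance`, sorted by lnc then
#'   distance then gene.
#' @export
find_cis_candidates <- function(ann, window_bp = 1e5, lnc_ids = NULL) {
  stopifnot(inherits(ann, "lnc_annotation"))
  lncs <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]
  if (!is.null(lnc_ids)) lncs <- lncs[lncs$transcript_id %in% lnc_ids, ]
  genes <- gene_spans(ann)
  if (nrow(lncs) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(lnc = character(), gene = character(), distance = double()))
  }
  out <- purrr::map_dfr(seq_len(nrow(lncs)), function(i) {
    l <- lncs[i, ]
    g <- genes[genes$chrom == l$chrom, ]
    if (nrow(g) == 0) return(NULL)
    d <- span_distance(l$start, l$end, g$start, g$end)
    keep <- d <= window_bp
    tibble::tibble(lnc = l$transcript_id, gene = g$gene_id[keep], distance = d[keep])
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(lnc = character(), gene = character(), distance = double()))
  }
  dplyr::arrange(out, .data$lnc, .data$distance, .data$gene)
}

# protein-coding gene spans (union over the gene's transcripts)
gene_spans <- function(ann) {
  ann$transcripts |>
    dplyr::filter(.data$biotype == "protein_coding") |>
    dplyr::group_by(gene_id = .data$gene_id, chrom = .data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     strand = .data$strand[1], .groups = "drop")
}

#' Correlate candidate pairs and keep cis targets
#'
#' Pearson correlation across all samples; a pair is retained when
#' r strictly exceeds `r_min` (default 0.6; positive correlation only).
#' Pairs involving a zero-variance profile are dropped with a warning.
#'
#' @param pairs tibble with columns `lnc`, `gene` (e.g. from
#'   [find_cis_candidates()]; extra columns such as `distance` are carried
#'   through).
#' @param expr expression tibble containing both features of every pair.
#' @param r_min correlation threshold, strict (default 0.6).
#' @return `pairs` rows that qualify, with an added `r` column.
#' @export
correlate_and_select <- function(pairs, expr, r_min = 0.6) {
  assert_expr(expr)
  m <- counts_matrix(expr)
  if (ncol(m) < 3) stop("need at least 3 samples to correlate", call. = FALSE)
  missing <- setdiff(unique(c(pairs$lnc, pairs$gene)), rownames(m))
  if (length(missing)) {
    stop("features absent from `expr`: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) == 0) return(dplyr::mutate(pairs, r = double()))
  v <- apply(m, 1, stats::var)
  degenerate <- v[pairs$lnc] == 0 | v[pairs$gene] == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) dropped: zero-variance expression profile",
            call. = FALSE)
  }
  pairs <- pairs[!degenerate, , drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)),
              function(i) stats::cor(m[pairs$lnc[i], ], m[pairs$gene[i], ]),
              numeric(1))
  out <- dplyr::mutate(pairs, r = r)
  out[r > r_min, , drop = FALSE]
}

#' Nearest protein-coding gene for each lncRNA
#'
#' Minimal edge-to-edge span distance on the lncRNA's chromosome; ties go to
#' the lexicographically smaller gene id. lncRNAs on a chromosome without
#' coding genes get an NA gene.
#'
#' @inheritParams find_cis_candidates
#' @return tibble with columns `lnc`, `gene`, `distance`.
#' @export
nearest_coding_gene <- function(ann, lnc_ids = NULL) {
  stopifnot(inherits(ann, "lnc_annotation"))
  lncs <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]
  if (!is.null(lnc_ids)) lncs <- lncs[lncs$transcript_id %in% lnc_ids, ]
  genes <- gene_spans(ann)
  purrr::map_dfr(seq_len(nrow(lncs)), function(i) {
    l <- lncs[i, ]
    g <- genes[genes$chrom == l$chrom, ]
    if (nrow(g) == 0) {
      return(tibble::tibble(lnc = l$transcript_id, gene = NA_character_,
                            distance = NA_real_))
    }
    d <- span_distance(l$start, l$end, g$start, g$end)
    ord <- order(d, g$gene_id)
    tibble::tibble(lnc = l$transcript_id, gene = g$gene_id[ord[1]],
                   distance = d[ord[1]])
  })
}
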