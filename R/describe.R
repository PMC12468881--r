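#' Genomic-context classification of lncRNAs
#'
#' Each lncRNA is placed relative to the protein-coding annotation using the
#' precedence exonic > intronic > upstream > downstream > intergenic:
#' \itemize{
#'   \item exonic: any lncRNA exon overlaps any coding exon by >= 1 bp;
#'   \item intronic: the lncRNA span lies entirely within a coding
#'     transcript's span (so it touches introns only);
#'   \item upstream: the span overlaps the `window_bp` region 5' of a coding
#'     TSS (strand-aware for the coding gene);
#'   \item downstream: likewise 3' of a coding transcript's end;
#'   \item intergenic otherwise.
#' }
#' The partner is the coding transcript's gene that triggers the category,
#' ties broken by smaller span-to-span distance then lexicographic gene id.
#' Orientation is relational: `sense` when the lncRNA strand equals the
#' partner's strand, `antisense` when opposite, `unassigned` when there is
#' no partner or either strand is `"."`.
#'
#' @param ann an `lnc_annotation` containing both lncRNA and protein-coding
#'   transcripts.
#' @param window_bp upstream/downstream neighbourhood size in bp
#'   (default 10000).
#' @param lnc_ids optional subset of lncRNA transcript ids to classify.
#' @return tibble with columns `transcript_id`, `category`, `orientation`,
#'   `partner_gene` (NA for intergenic).
#' @export
classify_context <- function(ann, window_bp = 10000, lnc_ids = NULL) {
  stopifnot(inherits(ann, "lnc_annotation"), window_bp > 0)
  tx <- ann$transcripts
  lncs <- tx[tx$biotype == "lncRNA", ]
  if (!is.null(lnc_ids)) lncs <- lncs[lncs$transcript_id %in% lnc_ids, ]
  coding <- tx[tx$biotype == "protein_coding", ]
  cexons <- ann$exons[ann$exons$biotype == "protein_coding", ]
  lexons <- ann$exons[ann$exons$biotype == "lncRNA", ]

  cod_by_chrom <- split(coding, coding$chrom)
  cex_by_chrom <- split(cexons, cexons$chrom)
  lex_by_tx <- split(lexons, lexons$transcript_id)

  one <- function(i) {
    l <- lncs[i, ]
    cod <- cod_by_chrom[[l$chrom]]
    if (is.null(cod) || nrow(cod) == 0) {
      return(list(category = "intergenic", partner = NA_character_,
                  partner_strand = NA_character_))
    }
    pick <- function(cands) {
      d <- span_distance(l$start, l$end, cands$start, cands$end)
      cands <- cands[order(d, cands$gene_id), ]
      list(partner = cands$gene_id[1], partner_strand = cands$strand[1])
    }
    # exonic
    le <- lex_by_tx[[l$transcript_id]]
    ce <- cex_by_chrom[[l$chrom]]
    if (!is.null(ce) && nrow(ce)) {
      hit_tx <- unique(ce$transcript_id[vapply(seq_len(nrow(ce)), function(k) {
        any(le$start < ce$end[k] & ce$start[k] < le$end)
      }, logical(1))])
      if (length(hit_tx)) {
        return(c(list(category = "exonic"), pick(cod[cod$transcript_id %in% hit_tx, ])))
      }
    }
    # intronic: span contained in a coding span
    inside <- cod[cod$start <= l$start & cod$end >= l$end, ]
    if (nrow(inside)) {
      return(c(list(category = "intronic"), pick(inside)))
    }
    # upstream / downstream windows (strand of the coding transcript)
    up_start <- ifelse(cod$strand == "-", cod$end, pmax(0, cod$start - window_bp))
    up_end <- ifelse(cod$strand == "-", cod$end + window_bp, cod$start)
    hits_up <- cod[l$start < up_end & up_start < l$end, ]
    if (nrow(hits_up)) {
      return(c(list(category = "upstream"), pick(hits_up)))
    }
    dn_start <- ifelse(cod$strand == "-", pmax(0, cod$start - window_bp), cod$end)
    dn_end <- ifelse(cod$strand == "-", cod$start, cod$end + window_bp)
    hits_dn <- cod[l$start < dn_end & dn_start < l$end, ]
    if (nrow(hits_dn)) {
      return(c(list(category = "downstream"), pick(hits_dn)))
    }
    list(category = "intergenic", partner = NA_character_,
         partner_strand = NA_character_)
  }

  res <- purrr::map(seq_len(nrow(lncs)), one)
  out <- tibble::tibble(
    transcript_id = lncs$transcript_id,
    category = purrr::map_chr(res, "category"),
    partner_gene = purrr::map_chr(res, "partner"),
    partner_strand = purrr::map_chr(res, "partner_strand"),
    strand = lncs$strand
  )
  out |>
    dplyr::mutate(
      orientation = dplyr::case_when(
        is.na(.data$partner_gene) ~ "unassigned",
        .data$strand == "." | .data$partner_strand == "." ~ "unassigned",
        .data$strand == .data$partner_strand ~ "sense",
        TRUE ~ "antisense"
      )
    ) |>
    dplyr::select("transcript_id", "category", "orientation", "partner_gene")
}

#' Sense/antisense split of context labels
#'
#' @param contexts tibble from [classify_context()].
#' @return tibble with columns `orientation`, `n`, `fraction`, restricted to
#'   assigned labels; fractions sum to 1.
#' @export
strand_split <- function(contexts) {
  assigned <- contexts[contexts$orientation %in% c("sense", "antisense"), ]
  if (nrow(assigned) == 0) {
    stop("no lncRNA has an assigned orientation", call. = FALSE)
  }
  tibble::tibble(orientation = c("sense", "antisense")) |>
    dplyr::mutate(
      n = vapply(.data$orientation,
                 function(o) sum(assigned$orientation == o), numeric(1),
                 USE.NAMES = FALSE),
      fraction = .data$n / nrow(assigned)
    )
}

#' Per-tissue context proportions
#'
#' @param contexts tibble from [classify_context()] for one tissue's
#'   expressed lncRNAs.
#' @param group label attached to the output.
#' @return tibble of class with one row per category: `group`, `category`,
#'   `n`, `proportion` (summing to 1 over categories present).
#' @export
context_proportions <- function(contexts, group = NA_character_) {
  if (nrow(contexts) == 0) {
    return(tibble::tibble(group = character(), category = character(),
                          n = integer(), proportion = double()))
  }
  contexts |>
    dplyr::count(category = .data$category) |>
    dplyr::mutate(group = group, proportion = .data$n / sum(.data$n)) |>
    dplyr::select("group", "category", "n", "proportion")
}

#' Spliced-length histogram
#'
#' Bins lncRNA spliced lengths into `[k * w, (k + 1) * w)` bins. Lengths at
#' or below 200 nt violate the lncRNA definition (> 200 nt) and trigger a
#' warning (or an error with `short = "error"`).
#'
#' @param x an `lnc_annotation` (its lncRNA transcripts are used) or a
#'   numeric vector of spliced lengths.
#' @param bin_width bin width in nt (default 100).
#' @param short what to do with lengths <= 200: `"warn"` (default) or
#'   `"error"`.
#' @return tibble of class `lnc_length_hist` with columns `bin_start`,
#'   `bin_end`, `label` (e.g. `"800-900"`), `count`, covering the occupied
#'   range contiguously.
#' @export
length_histogram <- function(x, bin_width = 100, short = c("warn", "error")) {
  short <- match.arg(short)
  lengths <- if (inherits(x, "lnc_annotation")) {
    x$transcripts$spliced_length[x$transcripts$biotype == "lncRNA"]
  } else {
    as.numeric(x)
  }
  if (any(lengths <= 200)) {
    msg <- paste0(sum(lengths <= 200), " length(s) <= 200 nt violate the lncRNA definition")
    if (short == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!length(lengths)) {
    out <- tibble::tibble(bin_start = integer(), bin_end = integer(),
                          label = character(), count = integer())
  } else {
    k <- floor(lengths / bin_width)
    bins <- seq(min(k), max(k))
    out <- tibble::tibble(
      bin_start = as.integer(bins * bin_width),
      bin_end = as.integer((bins + 1) * bin_width),
      label = paste0(bins * bin_width, "-", (bins + 1) * bin_width),
      count = as.integer(vapply(bins, function(b) sum(k == b), numeric(1)))
    )
  }
  class(out) <- c("lnc_length_hist", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Modal bin of a length histogram
#' @param hist a `lnc_length_hist`.
#' @return one-row tibble (the lowest bin on ties).
#' @export
modal_length_bin <- function(hist) {
  stopifnot(nrow(hist) > 0)
  hist[which.max(hist$count), ]
}

#' @export
autoplot.lnc_length_hist <- function(object, ...) {
  bw <- attr(object, "bin_width")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start + bw / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::labs(x = "spliced length (nt)", y = "lncRNA count",
                  title = "lncRNA spliced-length distribution")
}

#' Per-chromosome lncRNA counts and densities
#'
#' @param ann an `lnc_annotation`.
#' @return tibble with columns `chrom`, `n`, `density_per_mb`
#'   (`n / (size / 1e6)`), one row per chromosome in `chrom_sizes`
#'   (zero counts included).
#' @export
chromosome_stats <- function(ann) {
  stopifnot(inherits(ann, "lnc_annotation"))
  lncs <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]
  missing <- setdiff(unique(lncs$chrom), ann$chrom_sizes$chrom)
  if (length(missing)) {
    stop("no size for chromosome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann$chrom_sizes |>
    dplyr::mutate(
      n = vapply(.data$chrom, function(ch) sum(lncs$chrom == ch),
                 numeric(1), USE.NAMES = FALSE),
      density_per_mb = .data$n / (.data$size / 1e6)
    ) |>
    dplyr::select("chrom", "n", "density_per_mb")
}

#' Welch two-sample t-test on per-sample proportions
#'
#' Used to compare the positional distribution of lncRNAs between tissue
#' groups. Degenerate inputs (zero variance on both sides) give p = 1 when
#' the means are equal and p = 0 otherwise.
#'
#' @param a,b numeric vectors of per-sample proportions (length >= 2 each).
#' @return two-sided p-value.
#' @export
compare_proportions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}
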