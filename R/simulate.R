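#' Simulate a genome annotation with planted genomic contexts
#'
#' Places protein-coding genes on evenly spaced slots (3 exons, introns of
#' 6-9 kb) and lncRNAs in positions that realize a configured mix of
#' genomic contexts (exonic / intronic / upstream / downstream / intergenic)
#' and a configured sense fraction, so [classify_context()] recovers the
#' planted labels exactly. lncRNAs are single-exon with spliced lengths
#' drawn from a log-normal whose mode sits inside the 800-900 nt bin,
#' truncated to (200, 5000] nt.
#'
#' @param n_genes,n_lncs,n_chroms numbers of coding genes, lncRNAs and
#'   chromosomes.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param context_mix named numeric mix over
#'   `c(exonic, intronic, upstream, downstream, intergenic)`; normalized to
#'   sum 1.
#' @param sense_frac fraction of non-intergenic lncRNAs on the partner's
#'   strand (default 0.25).
#' @param window_bp upstream/downstream window the placement respects
#'   (default 10000, matching [classify_context()]'s default).
#' @param length_meanlog,length_sdlog log-normal spliced-length parameters;
#'   defaults put the distribution mode at 850 nt.
#' @return list with `annotation` (an `lnc_annotation`) and `truth`
#'   (tibble `transcript_id`, `category`, `orientation`, `partner_gene`).
#' @export
simulate_annotation <- function(n_genes = 200, n_lncs = 500, n_chroms = 3,
                                seed = 1,
                                context_mix = c(exonic = 0.5, intronic = 0.3,
                                                upstream = 0.1, downstream = 0.1,
                                                intergenic = 0),
                                sense_frac = 0.25, window_bp = 10000,
                                length_meanlog = log(850) + 0.09,
                                length_sdlog = 0.3) {
  stopifnot(n_genes >= 1, n_lncs >= 0, n_chroms >= 1, all(context_mix >= 0))
  set.seed(seed)
  pitch <- 60000L

  # coding genes: 3 exons, placed one per slot
  chrom_of_gene <- rep(seq_len(n_chroms), length.out = n_genes)
  slot_of_gene <- as.integer(stats::ave(seq_len(n_genes), chrom_of_gene,
                                        FUN = seq_along)) - 1L
  genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
    gstart <- slot_of_gene[i] * pitch + 15000L
    elen <- as.integer(round(stats::runif(3, 500, 2000)))
    ilen <- as.integer(round(stats::runif(2, 6000, 9000)))
    starts <- gstart + cumsum(c(0L, elen[1] + ilen[1], elen[2] + ilen[2]))
    tibble::tibble(
      transcript_id = sprintf("GT%04d", i),
      gene_id = sprintf("G%04d", i),
      biotype = "protein_coding",
      chrom = paste0("chr", chrom_of_gene[i]),
      start = starts, end = starts + elen,
      strand = sample(c("+", "-"), 1)
    )
  })
  gene_tbl <- genes |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                     e1_start = .data$start[1], e1_end = .data$end[1],
                     i1_start = .data$end[1], i1_end = .data$start[2],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")

  draw_len <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rlnorm(n, length_meanlog, length_sdlog)
      out <- c(out, x[x > 200 & x <= 5000])
    }
    as.integer(round(out[seq_len(n)]))
  }

  tail_cursor <- stats::setNames(
    rep(max(slot_of_gene + 1) * pitch + window_bp + 10000L, n_chroms),
    paste0("chr", seq_len(n_chroms))
  )
  mix <- context_mix / sum(context_mix)
  cats <- sample(names(mix), n_lncs, replace = TRUE, prob = mix)
  lens <- draw_len(n_lncs)

  id <- sprintf("LNC%05d", seq_len(n_lncs))
  l_chrom <- character(n_lncs)
  l_start <- integer(n_lncs)
  l_end <- integer(n_lncs)
  l_strand <- character(n_lncs)
  orientation <- character(n_lncs)
  partner <- rep(NA_character_, n_lncs)
  for (i in seq_len(n_lncs)) {
    cat_i <- cats[i]
    L <- lens[i]
    if (cat_i == "intergenic") {
      ch <- sample(names(tail_cursor), 1)
      s <- tail_cursor[[ch]]
      tail_cursor[[ch]] <- s + L + 2L * window_bp
      l_strand[i] <- sample(c("+", "-"), 1)
      orientation[i] <- "unassigned"
      e_start <- s; e_end <- s + L
    } else {
      g <- gene_tbl[sample.int(nrow(gene_tbl), 1), ]
      ch <- g$chrom
      sense <- stats::runif(1) < sense_frac
      l_strand[i] <- if (sense) g$strand else setdiff(c("+", "-"), g$strand)
      partner[i] <- g$gene_id
      orientation[i] <- if (sense) "sense" else "antisense"
      if (cat_i == "exonic") {
        # start inside the first coding exon -> guaranteed exon overlap
        e_start <- g$e1_start + sample.int(g$e1_end - g$e1_start, 1) - 1L
        e_end <- e_start + L
      } else if (cat_i == "intronic") {
        gap <- g$i1_end - g$i1_start
        Lfit <- min(L, gap - 2L)
        e_start <- g$i1_start + 1L +
          sample.int(max(1L, gap - Lfit - 1L), 1) - 1L
        e_end <- e_start + Lfit
      } else {
        five_prime <- (cat_i == "upstream")
        left_side <- xor(g$strand == "-", five_prime)  # window left of the span?
        if (left_side) {
          e_start <- g$start - window_bp + sample.int(window_bp - L, 1) - 1L
          e_end <- e_start + L
        } else {
          e_start <- g$end + sample.int(window_bp - L, 1) - 1L
          e_end <- e_start + L
        }
      }
    }
    l_chrom[i] <- ch
    l_start[i] <- as.integer(e_start)
    l_end[i] <- as.integer(e_end)
  }
  lnc_exons <- tibble::tibble(
    transcript_id = id, gene_id = id, biotype = "lncRNA",
    chrom = l_chrom, start = l_start, end = l_end, strand = l_strand
  )
  exons <- dplyr::bind_rows(genes, lnc_exons)
  sizes <- exons |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(size = max(.data$end) + 50000L, .groups = "drop")
  list(
    annotation = annotation(exons, sizes),
    truth = tibble::tibble(transcript_id = id, category = cats,
                           orientation = orientation, partner_gene = partner) |>
      dplyr::arrange(.data$transcript_id)
  )
}

#' Simulate a multi-tissue count matrix with planted classes
#'
#' Counts are negative-binomial around a planted mean model:
#' \itemize{
#'   \item housekeeping features share one high baseline across all tissues
#'     (expected cross-tissue CV well below 1);
#'   \item tissue-specific features have a home tissue at `ts_fold` (default
#'     10) times their baseline in every other tissue;
#'   \item background features are elevated in exactly two tissues, with the
#'     top fold drawn from U(20, 40) and the second at the top divided by
#'     U(1.5, 2), so their realized cross-tissue CV stays above 1 (never
#'     housekeeping) while the top/second ratio stays below 3 (never
#'     tissue-specific).
#' }
#'
#' @param features character vector of feature ids, an `lnc_annotation`
#'   (its lncRNA ids are used), or a single integer count.
#' @param tissues tissue labels (default 5 tissues).
#' @param n_per_tissue samples per tissue (default 4).
#' @param n_hk,n_ts numbers of planted housekeeping / tissue-specific
#'   features; `n_hk + n_ts` must not exceed the feature count.
#' @param seed integer seed.
#' @param dispersion negative-binomial size parameter (default 10).
#' @param hk_level,ts_base,bg_base median expression levels of the three
#'   populations.
#' @param ts_fold home-tissue fold change for planted tissue-specific
#'   features (default 10; the classifier only requires 3).
#' @return list with `counts` (tibble), `groups` (tibble `sample`, `group`),
#'   and `truth` (list with `hk` id vector and `ts` tibble
#'   `feature`/`tissue`).
#' @export
simulate_counts <- function(features, tissues = paste0("T", 1:5),
                            n_per_tissue = 4, n_hk = 200, n_ts = 300,
                            seed = 1, dispersion = 10,
                            hk_level = 300, ts_base = 40, bg_base = 5,
                            ts_fold = 10) {
  if (inherits(features, "lnc_annotation")) {
    features <- features$transcripts$transcript_id[
      features$transcripts$biotype == "lncRNA"]
  } else if (is.numeric(features) && length(features) == 1) {
    features <- sprintf("LNC%05d", seq_len(features))
  }
  n <- length(features)
  if (n_hk + n_ts > n) stop("n_hk + n_ts exceeds the number of features", call. = FALSE)
  set.seed(seed)
  tissues <- sort(tissues)
  k <- length(tissues)
  if (k < 2) stop("need at least two tissues", call. = FALSE)

  roles <- rep("bg", n)
  planted <- sample.int(n, n_hk + n_ts)
  roles[planted[seq_len(n_hk)]] <- "hk"
  if (n_ts > 0) roles[planted[n_hk + seq_len(n_ts)]] <- "ts"
  home <- rep(NA_character_, n)
  home[roles == "ts"] <- sample(tissues, n_ts, replace = TRUE)

  mu <- matrix(0, n, k, dimnames = list(features, tissues))
  for (i in seq_len(n)) {
    if (roles[i] == "hk") {
      mu[i, ] <- stats::rlnorm(1, log(hk_level), 0.3)
    } else if (roles[i] == "ts") {
      base <- stats::rlnorm(1, log(ts_base), 0.3)
      mu[i, ] <- base
      mu[i, home[i]] <- base * ts_fold
    } else {
      base <- stats::rlnorm(1, log(bg_base), 0.6)
      m <- rep(1, k)
      hi <- sample.int(k, 2)
      top <- stats::runif(1, 20, 40)
      m[hi[1]] <- top
      m[hi[2]] <- top / stats::runif(1, 1.5, 2)
      mu[i, ] <- base * m
    }
  }
  samples <- paste0(rep(tissues, each = n_per_tissue), "_S",
                    rep(seq_len(n_per_tissue), times = k))
  groups <- tibble::tibble(sample = samples,
                           group = rep(tissues, each = n_per_tissue))
  counts <- matrix(0L, n, length(samples), dimnames = list(features, samples))
  for (j in seq_along(samples)) {
    counts[, j] <- stats::rnbinom(n, size = dispersion, mu = mu[, groups$group[j]])
  }
  list(
    counts = matrix_to_tbl(counts),
    groups = groups,
    truth = list(
      hk = sort(features[roles == "hk"]),
      ts = tibble::tibble(feature = features[roles == "ts"],
                          tissue = home[roles == "ts"]) |>
        dplyr::arrange(.data$feature)
    )
  )
}

#' Simulate lifted cross-species coordinates with known conservation
#'
#' Emulates liftOver output: a `frac_conserved` subset of foreign source
#' lncRNAs gets an interval guaranteed to overlap a randomly chosen pig
#' lncRNA (start jittered by up to `jitter_bp` while preserving >= 1 bp of
#' overlap); the remaining mapped sources get intervals placed in
#' guaranteed lncRNA-free gaps, so [call_conserved()] separates the two
#' groups perfectly by construction.
#'
#' @param ann pig `lnc_annotation`.
#' @param n_source number of foreign source lncRNAs.
#' @param frac_conserved fraction of sources planted as conserved.
#' @param jitter_bp maximum start jitter for conserved intervals.
#' @param frac_unmapped fraction of sources with no lifted fragment.
#' @param seed integer seed.
#' @param species label used in source ids.
#' @return list with `lifted` (BED tibble), `unmapped` (id vector) and
#'   `truth` (tibble `source_id`, `conserved`).
#' @export
simulate_lifted <- function(ann, n_source = 500, frac_conserved = 0.1,
                            jitter_bp = 50, frac_unmapped = 0.1, seed = 1,
                            species = "human") {
  stopifnot(inherits(ann, "lnc_annotation"),
            frac_conserved >= 0, frac_conserved <= 1)
  set.seed(seed)
  pig <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]
  if (nrow(pig) == 0) stop("annotation has no lncRNA transcripts", call. = FALSE)
  ids <- sprintf("%s_LNC%05d", toupper(substr(species, 1, 3)), seq_len(n_source))
  n_cons <- round(frac_conserved * n_source)
  n_unmapped <- min(round(frac_unmapped * n_source), n_source - n_cons)
  status <- c(rep("conserved", n_cons),
              rep("unmapped", n_unmapped),
              rep("background", n_source - n_cons - n_unmapped))
  status <- sample(status)

  gaps <- lnc_free_gaps(ann, min_width = 4000L)
  if (nrow(gaps) == 0 && any(status == "background")) {
    stop("no lncRNA-free gap available to place non-conserved intervals",
         call. = FALSE)
  }
  rows <- vector("list", n_source)
  for (i in seq_len(n_source)) {
    if (status[i] == "unmapped") next
    if (status[i] == "conserved") {
      p <- pig[sample.int(nrow(pig), 1), ]
      width <- max(200L, as.integer(round((p$end - p$start) * stats::runif(1, 0.6, 1.2))))
      jit <- sample.int(2L * jitter_bp + 1L, 1) - jitter_bp - 1L
      s <- p$start + jit
      # clamp so at least 1 bp of the pig span is covered
      s <- max(min(s, p$end - 1L), max(0L, p$start - width + 1L))
      rows[[i]] <- tibble::tibble(chrom = p$chrom, start = as.integer(s),
                                  end = as.integer(s + width), name = ids[i],
                                  score = 0, strand = sample(c("+", "-"), 1))
    } else {
      g <- gaps[sample.int(nrow(gaps), 1), ]
      width <- as.integer(round(stats::runif(1, 300, 1500)))
      width <- min(width, as.integer(g$end - g$start - 2L))
      s <- g$start + sample.int(g$end - g$start - width - 1L, 1)
      rows[[i]] <- tibble::tibble(chrom = g$chrom, start = as.integer(s),
                                  end = as.integer(s + width), name = ids[i],
                                  score = 0, strand = sample(c("+", "-"), 1))
    }
  }
  list(
    lifted = dplyr::bind_rows(rows),
    unmapped = ids[status == "unmapped"],
    truth = tibble::tibble(source_id = ids, conserved = status == "conserved") |>
      dplyr::arrange(.data$source_id)
  )
}

# maximal intervals free of lncRNA spans, per chromosome
lnc_free_gaps <- function(ann, min_width = 2000L) {
  pig <- ann$transcripts[ann$transcripts$biotype == "lncRNA", ]
  purrr::map_dfr(seq_len(nrow(ann$chrom_sizes)), function(i) {
    ch <- ann$chrom_sizes$chrom[i]
    size <- ann$chrom_sizes$size[i]
    spans <- pig[pig$chrom == ch, c("start", "end")]
    spans <- spans[order(spans$start), ]
    if (nrow(spans)) {
      merged_end <- cummax(spans$end)
      gap_start <- c(0, merged_end)
      gap_end <- c(spans$start, size)
      keep <- gap_end - gap_start >= min_width
      tibble::tibble(chrom = ch, start = gap_start[keep], end = gap_end[keep])
    } else {
      tibble::tibble(chrom = ch, start = 0, end = size)
    }
  })
}

#' Simulate a differential-expression table with planted effects
#'
#' Planted DE rows receive |log2FC| >= `effect_lfc` and p-values near
#' `p_de`; null rows receive log2FC ~ N(0, 0.2) and uniform p-values, so
#' [select_de()] after BH adjustment recovers the planted set at the
#' default thresholds.
#'
#' @param features feature ids.
#' @param contrasts contrast labels (one DE table row per feature per
#'   contrast).
#' @param n_de number of planted DE features per contrast.
#' @param effect_lfc minimum absolute planted log2 fold change (default 2).
#' @param p_de planted p-value scale (default 1e-6).
#' @param seed integer seed.
#' @return list with `de` (tibble `feature`, `contrast`, `log2fc`, `p`) and
#'   `truth` (tibble `feature`, `contrast`, `log2fc` of planted rows).
#' @export
simulate_de <- function(features, contrasts = "AF1_vs_AF5", n_de = 50,
                        effect_lfc = 2, p_de = 1e-6, seed = 1) {
  if (is.numeric(features) && length(features) == 1) {
    features <- sprintf("LNC%05d", seq_len(features))
  }
  stopifnot(n_de <= length(features))
  set.seed(seed)
  out <- purrr::map_dfr(contrasts, function(ct) {
    de_idx <- sample.int(length(features), n_de)
    lfc <- stats::rnorm(length(features), 0, 0.2)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      (effect_lfc + stats::rexp(n_de, 2))
    p <- stats::runif(length(features))
    p[de_idx] <- p_de * stats::runif(n_de)
    tibble::tibble(feature = features, contrast = ct, log2fc = lfc, p = p,
                   planted = seq_along(features) %in% de_idx)
  })
  list(
    de = dplyr::select(out, -"planted"),
    truth = out |>
      dplyr::filter(.data$planted) |>
      dplyr::select("feature", "contrast", "log2fc") |>
      dplyr::arrange(.data$contrast, .data$feature)
  )
}

#' Simulate miRNA interaction edge tables
#'
#' Scores are uniform on (100, 200) and energies uniform on (-40, 0), so
#' roughly a quarter of the edges survive the score > 140, energy < -20
#' retention rule.
#'
#' @param sponges,mirnas,mrnas id vectors (or single integer counts).
#' @param n_edges number of sponge-miRNA and miRNA-mRNA edges each.
#' @param seed integer seed.
#' @return list with tibbles `sponge_mirna` and `mirna_mrna`, both with
#'   columns `source`, `target`, `score`, `energy`.
#' @export
simulate_interactions <- function(sponges = 50, mirnas = 20, mrnas = 100,
                                  n_edges = 300, seed = 1) {
  as_ids <- function(x, prefix) {
    if (is.numeric(x) && length(x) == 1) sprintf("%s%04d", prefix, seq_len(x)) else x
  }
  sponges <- as_ids(sponges, "LNC")
  mirnas <- as_ids(mirnas, "miR-")
  mrnas <- as_ids(mrnas, "G")
  set.seed(seed)
  edge_tbl <- function(src, tgt) {
    tibble::tibble(
      source = sample(src, n_edges, replace = TRUE),
      target = sample(tgt, n_edges, replace = TRUE),
      score = stats::runif(n_edges, 100, 200),
      energy = stats::runif(n_edges, -40, 0)
    ) |> dplyr::distinct(.data$source, .data$target, .keep_all = TRUE)
  }
  list(sponge_mirna = edge_tbl(sponges, mirnas),
       mirna_mrna = edge_tbl(mirnas, mrnas))
}

#' Simulate a complete atlas input bundle
#'
#' Fans one global seed out to fixed per-generator child seeds
#' (annotation +1, counts +2, liftover +3, DE +4, interactions +5), so each
#' stage is reproducible in isolation.
#'
#' @param seed global integer seed.
#' @param n_genes,n_lncs,n_chroms annotation sizes.
#' @param tissues,n_per_tissue,n_hk,n_ts count-matrix configuration.
#' @param n_source,frac_conserved liftover configuration.
#' @param n_de_per_contrast,contrasts DE configuration.
#' @param ... further arguments passed to [simulate_counts()].
#' @return list with elements `annotation`, `context_truth`, `counts`,
#'   `groups`, `class_truth`, `lifted`, `unmapped`, `conserved_truth`,
#'   `de`, `de_truth`, `edges`, `config`.
#' @export
simulate_atlas <- function(seed = 42, n_genes = 300, n_lncs = 2000,
                           n_chroms = 5, tissues = paste0("T", 1:5),
                           n_per_tissue = 4, n_hk = 200, n_ts = 300,
                           n_source = 500, frac_conserved = 0.1,
                           n_de_per_contrast = 50,
                           contrasts = c("AF1_vs_AF3", "AF1_vs_AF5"), ...) {
  ann <- simulate_annotation(n_genes = n_genes, n_lncs = n_lncs,
                             n_chroms = n_chroms, seed = seed + 1)
  cm <- simulate_counts(ann$annotation, tissues = tissues,
                        n_per_tissue = n_per_tissue, n_hk = n_hk, n_ts = n_ts,
                        seed = seed + 2, ...)
  lift <- simulate_lifted(ann$annotation, n_source = n_source,
                          frac_conserved = frac_conserved, seed = seed + 3)
  de <- simulate_de(cm$counts$feature, contrasts = contrasts,
                    n_de = n_de_per_contrast, seed = seed + 4)
  edges <- simulate_interactions(
    sponges = sample(cm$counts$feature, min(50, n_lncs)),
    seed = seed + 5
  )
  list(
    annotation = ann$annotation, context_truth = ann$truth,
    counts = cm$counts, groups = cm$groups, class_truth = cm$truth,
    lifted = lift$lifted, unmapped = lift$unmapped,
    conserved_truth = lift$truth,
    de = de$de, de_truth = de$truth,
    edges = edges,
    config = list(seed = seed, n_genes = n_genes, n_lncs = n_lncs,
                  n_chroms = n_chroms, tissues = tissues,
                  n_per_tissue = n_per_tissue, n_hk = n_hk, n_ts = n_ts,
                  n_source = n_source, frac_conserved = frac_conserved,
                  n_de_per_contrast = n_de_per_contrast, contrasts = contrasts)
  )
}
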