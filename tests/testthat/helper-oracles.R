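# Independent brute-force implementations used as oracles. Each one applies
# the defining clauses literally with plain loops, sharing no code with the
# package internals it checks.

oracle_filter <- function(counts, groups, min_reads = 10, min_samples = 3) {
  kept <- character()
  grp <- setNames(groups$group, groups$sample)
  for (i in seq_len(nrow(counts))) {
    ok <- FALSE
    for (g in unique(groups$group)) {
      smp <- groups$sample[groups$group == g]
      n_pass <- 0
      for (s in smp) if (counts[[s]][i] > min_reads) n_pass <- n_pass + 1
      if (n_pass >= min_samples) ok <- TRUE
    }
    if (ok) kept <- c(kept, counts$feature[i])
  }
  kept
}

# mean_mat: features x tissues matrix of normalized group means
oracle_hk <- function(mean_mat, cv_max = 1) {
  overall <- apply(mean_mat, 1, mean)
  med <- median(overall)
  out <- character()
  for (f in rownames(mean_mat)) {
    v <- mean_mat[f, ]
    cv <- if (mean(v) == 0) Inf else sd(v) / mean(v)
    if (overall[f] > med && cv < cv_max) out <- c(out, f)
  }
  sort(out)
}

oracle_ts <- function(mean_mat, rank_top = 0.25, share_min = 0.5, ratio_min = 3) {
  n <- nrow(mean_mat)
  out <- list()
  for (f in rownames(mean_mat)) {
    for (t in colnames(mean_mat)) {
      x <- mean_mat[f, t]
      rank_q <- if (n > 1) sum(mean_mat[, t] < x) / (n - 1) else 1
      total <- sum(mean_mat[f, ])
      share <- if (total > 0) x / total else 0
      others <- mean_mat[f, setdiff(colnames(mean_mat), t)]
      ratio_ok <- if (max(others) == 0) x > 0 else x >= ratio_min * max(others)
      if (rank_q >= 1 - rank_top && share > share_min && x > 0 && ratio_ok) {
        out[[length(out) + 1]] <- data.frame(feature = f, tissue = t)
      }
    }
  }
  if (length(out)) do.call(rbind, out)[order(sapply(out, `[[`, "feature")), ] else
    data.frame(feature = character(), tissue = character())
}

# literal precedence classifier over exon tables (0-based half-open)
oracle_context <- function(lnc_exons, cod_exons, window = 10000) {
  lspan <- c(min(lnc_exons$start), max(lnc_exons$end))
  lchrom <- lnc_exons$chrom[1]
  cod_exons <- cod_exons[cod_exons$chrom == lchrom, ]
  if (nrow(cod_exons) == 0) {
    return(list(category = "intergenic", partner = NA_character_))
  }
  tx_ids <- unique(cod_exons$transcript_id)
  span_of <- function(id) {
    e <- cod_exons[cod_exons$transcript_id == id, ]
    c(min(e$start), max(e$end))
  }
  dist_to <- function(id) {
    s <- span_of(id)
    max(0, max(lspan[1], s[1]) - min(lspan[2], s[2]))
  }
  gene_of <- function(id) cod_exons$gene_id[cod_exons$transcript_id == id][1]
  pick <- function(ids) {
    d <- sapply(ids, dist_to)
    g <- sapply(ids, gene_of)
    ord <- order(d, g)
    unname(g[ord[1]])
  }
  hit <- character()
  for (id in tx_ids) {
    e <- cod_exons[cod_exons$transcript_id == id, ]
    for (i in seq_len(nrow(e))) for (j in seq_len(nrow(lnc_exons))) {
      if (lnc_exons$start[j] < e$end[i] && e$start[i] < lnc_exons$end[j]) hit <- c(hit, id)
    }
  }
  if (length(hit)) return(list(category = "exonic", partner = pick(unique(hit))))
  hit <- character()
  for (id in tx_ids) {
    s <- span_of(id)
    if (s[1] <= lspan[1] && s[2] >= lspan[2]) hit <- c(hit, id)
  }
  if (length(hit)) return(list(category = "intronic", partner = pick(hit)))
  for (side in c("upstream", "downstream")) {
    hit <- character()
    for (id in tx_ids) {
      s <- span_of(id)
      str <- cod_exons$strand[cod_exons$transcript_id == id][1]
      left <- if (side == "upstream") str == "+" else str == "-"
      win <- if (left) c(s[1] - window, s[1]) else c(s[2], s[2] + window)
      if (lspan[1] < win[2] && win[1] < lspan[2]) hit <- c(hit, id)
    }
    if (length(hit)) return(list(category = side, partner = pick(hit)))
  }
  list(category = "intergenic", partner = NA_character_)
}

oracle_conserved <- function(lifted, pig_spans, min_ov = 1) {
  out <- logical(0)
  for (nm in unique(lifted$name)) {
    frags <- lifted[lifted$name == nm, ]
    hit <- FALSE
    for (i in seq_len(nrow(frags))) for (j in seq_len(nrow(pig_spans))) {
      if (frags$chrom[i] == pig_spans$chrom[j]) {
        ov <- min(frags$end[i], pig_spans$end[j]) - max(frags$start[i], pig_spans$start[j])
        if (ov >= min_ov) hit <- TRUE
      }
    }
    out[nm] <- hit
  }
  out
}

oracle_cis <- function(lnc_span, genes, window = 1e5) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != lnc_span$chrom) next
    d <- max(0, max(lnc_span$start, genes$start[i]) - min(lnc_span$end, genes$end[i]))
    if (d <= window) out[[length(out) + 1]] <- data.frame(gene = genes$gene_id[i], distance = d)
  }
  if (length(out)) do.call(rbind, out) else data.frame(gene = character(), distance = numeric())
}

oracle_hubs <- function(stats, mm_min = 0.8, gs_min = 0.2) {
  out <- character()
  for (i in seq_len(nrow(stats))) {
    mm <- stats$MM[i]; gs <- stats$GS[i]
    if (!is.na(mm) && !is.na(gs) && abs(mm) > mm_min && abs(gs) > gs_min) {
      out <- c(out, stats$feature[i])
    }
  }
  out
}

oracle_de <- function(de, fdr = 0.05, lfc = 1) {
  out <- character()
  for (i in seq_len(nrow(de))) {
    if (de$p_adj[i] < fdr && abs(de$log2fc[i]) >= lfc) out <- c(out, de$feature[i])
  }
  out
}

oracle_edges <- function(edges, score_min = 140, energy_max = -20) {
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    keep[i] <- edges$score[i] > score_min && edges$energy[i] < energy_max
  }
  edges[keep, , drop = FALSE]
}

oracle_cerna <- function(sm, mg) {
  out <- list()
  for (i in seq_len(nrow(sm))) for (j in seq_len(nrow(mg))) {
    if (sm$target[i] == mg$source[j]) {
      out[[length(out) + 1]] <- data.frame(sponge = sm$source[i],
                                           mirna = sm$target[i],
                                           mrna = mg$target[j])
    }
  }
  if (!length(out)) {
    return(data.frame(sponge = character(), mirna = character(), mrna = character()))
  }
  u <- unique(do.call(rbind, out))
  u[order(u$sponge, u$mirna, u$mrna), , drop = FALSE]
}

# quadratic min-over-suffix evaluation of the BH step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    i <- ord[pos]
    suffix <- Inf
    for (pos2 in pos:m) {
      k <- ord[pos2]
      suffix <- min(suffix, p[k] * m / pos2)
    }
    adj[i] <- min(1, suffix)
  }
  adj
}

oracle_welch <- function(a, b) {
  nx <- length(a); ny <- length(b)
  vx <- var(a); vy <- var(b)
  se2 <- vx / nx + vy / ny
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# random fixtures -------------------------------------------------------------

random_counts <- function(n_feat = 20, groups = c("A", "B", "C"), n_per = 4,
                          lambda = 15) {
  samples <- paste0(rep(groups, each = n_per), seq_len(n_per))
  m <- matrix(rpois(n_feat * length(samples), lambda), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)), samples))
  list(
    counts = tibble::as_tibble(m, rownames = "feature"),
    groups = tibble::tibble(sample = samples, group = rep(groups, each = n_per))
  )
}

# random multi-exon transcript models for round-trip tests
random_annotation <- function(n_tx = 50) {
  rows <- list()
  for (i in seq_len(n_tx)) {
    n_ex <- sample(1:4, 1)
    start0 <- sample.int(1e6, 1)
    widths <- sample(100:2000, n_ex, replace = TRUE)
    gaps <- sample(50:5000, n_ex, replace = TRUE)
    starts <- start0 + cumsum(c(0, head(widths + gaps, -1)))
    rows[[i]] <- tibble::tibble(
      transcript_id = sprintf("TX%04d", i),
      gene_id = sprintf("GN%04d", ceiling(i / 2)),
      biotype = sample(c("lncRNA", "protein_coding"), 1),
      chrom = sample(paste0("chr", 1:3), 1),
      start = as.integer(starts), end = as.integer(starts + widths),
      strand = sample(c("+", "-"), 1)
    )
  }
  annotation(dplyr::bind_rows(rows))
}

# random layout for context-classification oracle tests: genes may overlap
random_context_layout <- function(n_genes = 3) {
  rows <- list()
  for (i in seq_len(n_genes)) {
    n_ex <- sample(1:3, 1)
    start0 <- sample.int(80000, 1)
    widths <- sample(200:1500, n_ex, replace = TRUE)
    gaps <- sample(500:4000, n_ex, replace = TRUE)
    starts <- start0 + cumsum(c(0, head(widths + gaps, -1)))
    rows[[i]] <- tibble::tibble(
      transcript_id = sprintf("CT%02d", i), gene_id = sprintf("CG%02d", i),
      biotype = "protein_coding", chrom = "chr1",
      start = as.integer(starts), end = as.integer(starts + widths),
      strand = sample(c("+", "-"), 1)
    )
  }
  lnc_start <- sample.int(120000, 1)
  lnc <- tibble::tibble(
    transcript_id = "LX01", gene_id = "LX01", biotype = "lncRNA",
    chrom = "chr1", start = lnc_start,
    end = lnc_start + sample(300:3000, 1), strand = sample(c("+", "-"), 1)
  )
  list(cod = dplyr::bind_rows(rows), lnc = lnc)
}
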