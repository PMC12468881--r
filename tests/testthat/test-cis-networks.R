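cis_ann <- function(lnc_start, lnc_end, gene_starts, gene_ends,
                    chroms = "chr1") {
  genes <- tibble::tibble(
    transcript_id = sprintf("gt%02d", seq_along(gene_starts)),
    gene_id = sprintf("g%02d", seq_along(gene_starts)),
    biotype = "protein_coding",
    chrom = rep(chroms, length.out = length(gene_starts)),
    start = as.integer(gene_starts), end = as.integer(gene_ends), strand = "+"
  )
  lnc <- tibble::tibble(
    transcript_id = "L1", gene_id = "L1", biotype = "lncRNA",
    chrom = "chr1", start = as.integer(lnc_start), end = as.integer(lnc_end),
    strand = "+"
  )
  annotation(dplyr::bind_rows(genes, lnc))
}

test_that("cis candidates respect the +/-100 kb edge-to-edge window", {
  ann <- cis_ann(10000, 12000, c(62000, 1200000, 11000), c(63000, 1201000, 11500))
  cand <- find_cis_candidates(ann)
  expect_equal(cand$gene, c("g03", "g01"))            # overlap first (distance 0)
  expect_equal(cand$distance, c(0, 50000))            # 50 kb past the lnc end
  expect_false("g02" %in% cand$gene)                  # ~1.19 Mb away
})

test_that("cis candidates equal the brute-force distance scan", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    gs <- sample.int(5e5, n)
    ann <- cis_ann(2e5, 2e5 + 3000, gs, gs + sample.int(2e4, n),
                   chroms = sample(c("chr1", "chr2"), n, replace = TRUE))
    got <- find_cis_candidates(ann)
    genes <- dplyr::filter(ann$transcripts, biotype == "protein_coding")
    want <- oracle_cis(list(chrom = "chr1", start = 2e5, end = 2e5 + 3000),
                       genes, 1e5)
    want <- want[order(want$distance, want$gene), ]
    expect_equal(got$gene, want$gene)
    expect_equal(got$distance, want$distance)
  }
})

test_that("cis correlation keeps r > 0.6 strictly", {
  expr <- tibble::tibble(
    feature = c("L1", "same", "exact", "anti"),
    s1 = c(1, 1, NA, 4), s2 = c(2, 2, NA, 3), s3 = c(3, 3, NA, 2),
    s4 = c(4, 4, NA, 1), s5 = c(5, 5, NA, 0)
  )
  # build a profile with cor(L1, exact) == 0.6 exactly by solving for one entry
  base <- c(1, 2, 3, 4, 5)
  f <- function(a) cor(base, c(2, 1, 4, 3, a)) - 0.6
  a <- uniroot(f, c(3, 50))$root
  expr[expr$feature == "exact", -1] <- as.list(c(2, 1, 4, 3, a))
  pairs <- tibble::tibble(lnc = "L1", gene = c("same", "exact", "anti"))
  kept <- correlate_and_select(pairs, expr)
  expect_equal(kept$gene, "same")
  expect_equal(kept$r, 1)
  set.seed(52)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    e2 <- tibble::tibble(feature = c("a", "b"),
                         !!!setNames(as.data.frame(rbind(x, y)), paste0("s", 1:6)))
    r <- correlate_and_select(tibble::tibble(lnc = "a", gene = "b"), e2,
                              r_min = -2)$r
    expect_equal(r, oracle_pearson(x, y))
  }
})

test_that("zero-variance cis profiles are dropped with a warning", {
  expr <- tibble::tibble(feature = c("L1", "flat"), s1 = c(1, 2), s2 = c(2, 2),
                         s3 = c(3, 2))
  pairs <- tibble::tibble(lnc = "L1", gene = "flat")
  expect_warning(res <- correlate_and_select(pairs, expr), "zero-variance")
  expect_equal(nrow(res), 0)
})

test_that("nearest coding gene uses distance then lexicographic ties", {
  ann <- cis_ann(50000, 51000, c(49000, 52000), c(49500, 53000))
  # distances: g01 -> 500, g02 -> 1000
  expect_equal(nearest_coding_gene(ann)$gene, "g01")
  ann2 <- cis_ann(50000, 51000, c(48500, 52000), c(49000, 52500))
  # both at distance 1000 -> lexicographically smaller id
  expect_equal(nearest_coding_gene(ann2)$gene, "g01")
  ann3 <- cis_ann(50000, 51000, 50500, 50800)
  expect_equal(nearest_coding_gene(ann3)$distance, 0)
})

test_that("module eigengene matches an independent SVD and fixes sign", {
  # identical features: eigengene is the standardized common profile, MM = 1
  prof <- c(1, 3, 2, 5, 4, 6)
  expr <- tibble::tibble(feature = c("a", "b", "c"),
                         !!!setNames(as.data.frame(rbind(prof, prof, prof)),
                                     paste0("s", 1:6)))
  e <- module_eigengene(expr)
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(e$eigengene, z / sqrt(sum(z^2)))
  mm <- module_membership_gs(expr, e, trait = c(1, 1, 1, 0, 0, 0))
  expect_equal(mm$MM, c(1, 1, 1))

  # two opposite features: MMs are +1 and -1
  expr2 <- tibble::tibble(feature = c("a", "b"),
                          !!!setNames(as.data.frame(rbind(prof, -prof)),
                                      paste0("s", 1:6)))
  mm2 <- module_membership_gs(expr2, module_eigengene(expr2), trait = rep(0:1, 3))
  expect_equal(sort(mm2$MM), c(-1, 1))

  set.seed(53)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("f%02d", 1:10), paste0("s", 1:6)))
  e3 <- module_eigengene(tibble::as_tibble(m, rownames = "feature"))
  zz <- t(scale(t(m)))
  full <- svd(zz)                     # independent full decomposition
  v1 <- full$v[, 1]
  if (mean(cor(t(zz), v1)) < 0) v1 <- -v1
  expect_equal(e3$eigengene, v1)
  # sign convention: mean correlation with the eigengene is non-negative
  expect_gte(mean(cor(t(m), e3$eigengene)), 0)
})

test_that("GS is missing under a constant trait design", {
  prof <- c(1, 3, 2, 5)
  expr <- tibble::tibble(feature = c("a", "b"),
                         !!!setNames(as.data.frame(rbind(prof, prof * 2)),
                                     paste0("s", 1:4)))
  mm <- module_membership_gs(expr, module_eigengene(expr), trait = rep(1, 4))
  expect_true(all(is.na(mm$GS)))
  expect_false(any(is.na(mm$MM)))
})

test_that("hub selection is strict at both thresholds", {
  stats <- tibble::tibble(
    feature = c("hub", "mm_edge", "gs_edge", "na"),
    MM = c(0.85, 0.8, 0.9, NA),
    GS = c(0.25, 0.5, 0.2, 0.5)
  )
  res <- select_hubs(stats)
  expect_equal(res$feature[res$is_hub], "hub")
  set.seed(54)
  for (rep in 1:30) {
    st <- tibble::tibble(feature = sprintf("f%02d", 1:20),
                         MM = runif(20, -1, 1), GS = runif(20, -1, 1))
    got <- select_hubs(st)
    expect_equal(got$feature[got$is_hub], oracle_hubs(st))
  }
})

test_that("BH adjustment equals the quadratic step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(55)
  for (rep in 1:40) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p & adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in raw order
  }
})

test_that("DE selection: FDR strict, fold-change inclusive", {
  de <- tibble::tibble(
    feature = c("in", "edge_p", "edge_lfc", "tiny_fc"),
    log2fc = c(1.0, 2, 1.0, 0),
    p_adj = c(0.049, 0.05, 0.01, 1e-9)
  )
  res <- select_de(de)
  expect_equal(res$feature[res$is_de], c("in", "edge_lfc"))
  set.seed(56)
  for (rep in 1:30) {
    d <- tibble::tibble(feature = sprintf("f%02d", 1:25),
                        log2fc = rnorm(25, 0, 1.5), p_adj = runif(25))
    got <- select_de(d)
    expect_equal(got$feature[got$is_de], oracle_de(d))
  }
})

test_that("select_de computes BH per contrast from raw p when needed", {
  de <- tibble::tibble(
    feature = rep(c("a", "b"), 2),
    contrast = rep(c("c1", "c2"), each = 2),
    log2fc = c(2, 2, 2, 2),
    p = c(0.01, 0.04, 0.5, 0.6)
  )
  res <- select_de(de)
  expect_equal(res$p_adj[res$contrast == "c1"], p.adjust(c(0.01, 0.04), "BH"))
  expect_equal(res$p_adj[res$contrast == "c2"], p.adjust(c(0.5, 0.6), "BH"))
})

test_that("interaction filter: score 140 and energy -20 are excluded", {
  edges <- tibble::tibble(
    source = "L1", target = paste0("m", 1:4),
    score = c(150, 140, 150, 141),
    energy = c(-25, -25, -20, -20.5)
  )
  kept <- filter_interactions(edges)
  expect_equal(kept$target, c("m1", "m4"))
  expect_warning(
    res <- filter_interactions(dplyr::mutate(edges, score = c(NA, 150, 150, 150))),
    "missing"
  )
  set.seed(57)
  for (rep in 1:30) {
    e <- tibble::tibble(source = "s", target = sprintf("t%02d", 1:20),
                        score = runif(20, 100, 200), energy = runif(20, -40, 0))
    expect_equal(filter_interactions(e), oracle_edges(e))
  }
})

test_that("ceRNA triples equal the nested-loop join oracle", {
  sm <- tibble::tibble(source = "L1", target = "miR-a")
  mg <- tibble::tibble(source = "miR-a", target = "G1")
  tr <- assemble_cerna(sm, mg)
  expect_equal(tr, tibble::tibble(sponge = "L1", mirna = "miR-a", mrna = "G1"))
  expect_equal(nrow(assemble_cerna(sm, tibble::tibble(source = "miR-z", target = "G1"))), 0)
  set.seed(58)
  for (rep in 1:30) {
    sm <- tibble::tibble(source = sample(paste0("L", 1:5), 15, TRUE),
                         target = sample(paste0("m", 1:4), 15, TRUE))
    mg <- tibble::tibble(source = sample(paste0("m", 1:4), 15, TRUE),
                         target = sample(paste0("G", 1:6), 15, TRUE))
    got <- assemble_cerna(sm, mg)
    want <- oracle_cerna(sm, mg)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$sponge, want$sponge)
    expect_equal(got$mirna, want$mirna)
    expect_equal(got$mrna, want$mrna)
    expect_lte(nrow(got), nrow(sm) * nrow(mg))
  }
})

test_that("sponge ranking exposes max and sum aggregation", {
  edges <- tibble::tibble(source = c("L1", "L1", "L2"), target = c("a", "b", "c"),
                          score = c(150, 160, 170))
  expect_equal(rank_sponges(edges, n = 1)$source, "L2")            # max: 170
  expect_equal(rank_sponges(edges, n = 1, aggregate = "sum")$source, "L1")  # 310
})
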