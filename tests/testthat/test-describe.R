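ctx_ann <- function(cod, lnc) annotation(dplyr::bind_rows(cod, lnc))

test_that("containment and intron cases classify with relational orientation", {
  cod <- tibble::tibble(
    transcript_id = "ct1", gene_id = "cg1", biotype = "protein_coding",
    chrom = "chr1", start = c(1000L, 5000L), end = c(2000L, 6000L), strand = "+"
  )
  inside_exon <- tibble::tibble(
    transcript_id = "l1", gene_id = "l1", biotype = "lncRNA",
    chrom = "chr1", start = 1200L, end = 1600L, strand = "-"
  )
  res <- classify_context(ctx_ann(cod, inside_exon))
  expect_equal(res$category, "exonic")
  expect_equal(res$orientation, "antisense")
  expect_equal(res$partner_gene, "cg1")

  in_intron <- tibble::tibble(
    transcript_id = "l2", gene_id = "l2", biotype = "lncRNA",
    chrom = "chr1", start = 2500L, end = 3500L, strand = "+"
  )
  res <- classify_context(ctx_ann(cod, in_intron))
  expect_equal(res$category, "intronic")
  expect_equal(res$orientation, "sense")

  upstream <- tibble::tibble(
    transcript_id = "l3", gene_id = "l3", biotype = "lncRNA",
    chrom = "chr1", start = 200L, end = 700L, strand = "-"
  )
  res <- classify_context(ctx_ann(cod, upstream))
  expect_equal(res$category, "upstream")

  far <- tibble::tibble(
    transcript_id = "l4", gene_id = "l4", biotype = "lncRNA",
    chrom = "chr1", start = 50000L, end = 51000L, strand = "+"
  )
  res <- classify_context(ctx_ann(cod, far))
  expect_equal(res$category, "intergenic")
  expect_equal(res$orientation, "unassigned")
  expect_true(is.na(res$partner_gene))
})

test_that("unknown lncRNA strand leaves orientation unassigned", {
  cod <- tibble::tibble(
    transcript_id = "ct1", gene_id = "cg1", biotype = "protein_coding",
    chrom = "chr1", start = 1000L, end = 2000L, strand = "+"
  )
  lnc <- tibble::tibble(
    transcript_id = "l1", gene_id = "l1", biotype = "lncRNA",
    chrom = "chr1", start = 1100L, end = 1500L, strand = "."
  )
  res <- classify_context(ctx_ann(cod, lnc))
  expect_equal(res$category, "exonic")
  expect_equal(res$orientation, "unassigned")
})

test_that("random layouts match the literal precedence oracle", {
  set.seed(31)
  for (rep in 1:100) {
    lay <- random_context_layout(sample(1:4, 1))
    got <- classify_context(ctx_ann(lay$cod, lay$lnc))
    want <- oracle_context(lay$lnc, lay$cod)
    expect_equal(got$category, want$category)
    expect_equal(got$partner_gene, want$partner)
  }
})

test_that("classification is idempotent and order-invariant", {
  set.seed(32)
  lay <- random_context_layout(3)
  ann1 <- ctx_ann(lay$cod, lay$lnc)
  ann2 <- ctx_ann(lay$cod[sample(nrow(lay$cod)), ], lay$lnc)
  expect_equal(classify_context(ann1), classify_context(ann2))
  expect_equal(classify_context(ann1), classify_context(ann1))
})

test_that("strand split computes fractions over assigned labels", {
  ctx <- tibble::tibble(
    transcript_id = paste0("l", 1:5),
    category = "exonic",
    orientation = c("sense", "antisense", "antisense", "antisense", "unassigned"),
    partner_gene = "g"
  )
  sp <- strand_split(ctx)
  expect_equal(sp$fraction, c(0.25, 0.75))
  expect_equal(sum(sp$fraction), 1)
  all_sense <- dplyr::mutate(ctx[1:2, ], orientation = "sense")
  expect_equal(strand_split(all_sense)$fraction, c(1, 0))
  none <- dplyr::mutate(ctx, orientation = "unassigned")
  expect_error(strand_split(none), "orientation")
  # order invariance
  set.seed(33)
  expect_equal(strand_split(ctx[sample(5), ]), sp)
})

test_that("length histogram bins by spliced length with the 800-900 label", {
  h <- length_histogram(c(850, 860, 250))
  expect_equal(modal_length_bin(h)$label, "800-900")
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(length_histogram(numeric())), 0)

  set.seed(34)
  lens <- sample(201:3000, 300, replace = TRUE)
  h2 <- length_histogram(lens)
  expect_equal(sum(h2$count), 300)
  for (i in sample(nrow(h2), 10)) {
    expect_equal(h2$count[i], sum(lens >= h2$bin_start[i] & lens < h2$bin_end[i]))
  }
  expect_warning(length_histogram(c(150, 900)), "200 nt")
  expect_error(length_histogram(c(150, 900), short = "error"), "200 nt")
})

test_that("chromosome counts and densities match direct arithmetic", {
  exons <- tibble::tibble(
    transcript_id = sprintf("l%02d", 1:10), gene_id = sprintf("l%02d", 1:10),
    biotype = "lncRNA", chrom = "chr1",
    start = seq(0L, 9e5L, 1e5L), end = seq(0L, 9e5L, 1e5L) + 500L, strand = "+"
  )
  ann <- annotation(exons, tibble::tibble(chrom = c("chr1", "chr2"),
                                          size = c(1e7, 5e6)))
  cs <- chromosome_stats(ann)
  expect_equal(cs$n[cs$chrom == "chr1"], 10)
  expect_equal(cs$density_per_mb[cs$chrom == "chr1"], 1)
  expect_equal(cs$n[cs$chrom == "chr2"], 0)
  expect_equal(cs$density_per_mb[cs$chrom == "chr2"], 0)
})

test_that("proportion comparison is a Welch t-test with degenerate cases handled", {
  expect_equal(compare_proportions(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2)), 1)
  expect_lt(compare_proportions(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9)), 0.01)
  set.seed(35)
  for (rep in 1:25) {
    a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1))
    expect_equal(compare_proportions(a, b), oracle_welch(a, b))
  }
})

test_that("context proportions sum to one per group", {
  set.seed(36)
  sim <- simulate_annotation(n_genes = 30, n_lncs = 120, seed = 5)
  ctx <- classify_context(sim$annotation)
  cp <- context_proportions(ctx, group = "liver")
  expect_equal(sum(cp$proportion), 1)
  expect_true(all(cp$proportion >= 0 & cp$proportion <= 1))
  expect_equal(sum(cp$n), nrow(ctx))
})
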