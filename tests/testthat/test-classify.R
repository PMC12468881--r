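# one sample per tissue -> group means equal the given matrix exactly
ts_from_means <- function(mean_mat) {
  expr <- tibble::as_tibble(mean_mat, rownames = "feature")
  groups <- tibble::tibble(sample = colnames(mean_mat), group = colnames(mean_mat))
  tissue_summary(expr, groups)
}

test_that("coefficient of variation follows the n-1 formula", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(c(1, 2, 3) * 17),
               coefficient_of_variation(c(1, 2, 3)))
  expect_equal(coefficient_of_variation(c(0, 0, 0)), Inf)
})

test_that("housekeeping excludes CV exactly 1 and single-tissue features", {
  # feature hkA: high flat; cv1: constructed so cv == 1 exactly; onehot: one tissue
  base <- c(10, 10, 10, 10)
  x <- c(2, 2, 2, 2)
  # vector with mean m and sd m has cv exactly 1: use (0, 0, m*2 - s, ...) trick
  cv1 <- c(4, 4, 4, 12)  # mean 6, sd 4 -> cv 2/3; replace with analytic below
  m <- rbind(hkA = base * 5, cv1 = cv1, onehot = c(40, 0, 0, 0), low = x)
  colnames(m) <- paste0("T", 1:4)
  # adjust cv1 so that sd/mean is exactly 1: (a, a, a, b) with b chosen analytically
  a <- 2
  b <- uniroot(function(b) sd(c(a, a, a, b)) / mean(c(a, a, a, b)) - 1,
               c(2.1, 100))$root
  m["cv1", ] <- c(a, a, a, b)
  ts <- ts_from_means(m)
  per <- dplyr::distinct(ts, feature, cv)
  expect_equal(per$cv[per$feature == "cv1"], 1, tolerance = 1e-6)
  hk <- classify_housekeeping(ts)
  expect_false("cv1" %in% hk)          # cv < 1 is strict
  expect_false("onehot" %in% hk)       # one-hot vector has cv 2 for 4 tissues
  expect_equal(hk, "hkA")
  expect_gt(per$cv[per$feature == "onehot"], 1)
})

test_that("tissue-specific rule: ratio 3 inclusive, share strict, unique tissue", {
  m <- rbind(
    spec = c(9, 3, 0, 0),        # top of T1: share 0.75, ratio exactly 3 -> in
    flat = c(5, 5, 5, 5),        # share 1/4 -> neither
    half = c(6, 6, 0, 0),        # share 0.5 exactly -> excluded (strict)
    top = c(1, 1, 1, 100)        # top of T4
  )
  colnames(m) <- paste0("T", 1:4)
  ts <- ts_from_means(m)
  res <- classify_tissue_specific(ts)
  expect_true(all(c("spec", "top") %in% res$feature))
  expect_equal(res$tissue[res$feature == "spec"], "T1")
  expect_equal(res$tissue[res$feature == "top"], "T4")
  expect_false("flat" %in% res$feature)
  expect_false("half" %in% res$feature)
})

test_that("classifiers equal the literal-clause oracle on random summaries", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(10:50, 1)
    k <- sample(3:6, 1)
    m <- matrix(rexp(n * k, 1 / 20) * rbinom(n * k, 1, 0.8), n, k,
                dimnames = list(sprintf("f%03d", 1:n), paste0("T", 1:k)))
    ts <- ts_from_means(m)
    expect_equal(classify_housekeeping(ts), oracle_hk(m))
    got <- classify_tissue_specific(ts)
    want <- oracle_ts(m)
    expect_equal(got$feature, want$feature)
    expect_equal(got$tissue, want$tissue)
  }
})

test_that("raising thresholds never enlarges a class", {
  set.seed(42)
  m <- matrix(rexp(200, 1 / 20), 50, 4,
              dimnames = list(sprintf("f%03d", 1:50), paste0("T", 1:4)))
  ts <- ts_from_means(m)
  expect_true(all(classify_housekeeping(ts, atlas_thresholds(cv_max = 0.5)) %in%
                    classify_housekeeping(ts)))
  strict <- classify_tissue_specific(ts, atlas_thresholds(ratio_min = 5,
                                                          share_min = 0.7,
                                                          rank_top = 0.1))
  expect_true(all(strict$feature %in% classify_tissue_specific(ts)$feature))
})

test_that("full classification recovers planted labels and is scale-invariant", {
  sim <- simulate_counts(400, tissues = paste0("T", 1:4), n_per_tissue = 3,
                         n_hk = 40, n_ts = 60, seed = 7)
  kept <- filter_expression(sim$counts, sim$groups)
  expr <- cpm_normalize(kept)
  cl <- classify_features(expr, sim$groups)

  hk_called <- cl$feature[cl$label == "housekeeping"]
  hk_true <- intersect(sim$truth$hk, kept$feature)
  expect_gte(sum(hk_called %in% hk_true) / length(hk_called), 0.9)
  expect_gte(mean(hk_true %in% hk_called), 0.9)

  ts_called <- cl[cl$label == "tissue_specific", c("feature", "tissue")]
  ts_true <- sim$truth$ts[sim$truth$ts$feature %in% kept$feature, ]
  tp <- nrow(dplyr::inner_join(ts_called, ts_true, by = c("feature", "tissue")))
  expect_gte(tp / nrow(ts_called), 0.9)
  expect_gte(tp / nrow(ts_true), 0.9)

  # a global positive rescaling leaves every label unchanged
  scaled <- expr
  scaled[, -1] <- scaled[, -1] * 7
  cl2 <- classify_features(scaled, sim$groups)
  expect_equal(cl2$label, cl$label)
  expect_equal(cl2$tissue, cl$tissue)

  # tissue-specific features double-qualifying as housekeeping resolve to TS
  expect_false(any(cl$label == "housekeeping" & !is.na(cl$tissue)))
})

test_that("degenerate classification inputs behave", {
  empty <- tibble::tibble(feature = character(), s1 = double(), s2 = double())
  groups <- tibble::tibble(sample = c("s1", "s2"), group = c("a", "b"))
  expect_equal(nrow(classify_features(empty, groups)), 0)

  zero <- tibble::tibble(feature = c("z", "p"), s1 = c(0, 5), s2 = c(0, 6))
  cl <- classify_features(zero, groups)
  expect_equal(cl$label[cl$feature == "z"], "neither")

  one_group <- tibble::tibble(sample = c("s1", "s2"), group = c("a", "a"))
  expect_error(classify_features(zero, one_group), "two tissues")
})

test_that("tidy and glance summarize a classification", {
  sim <- simulate_counts(60, n_hk = 10, n_ts = 10, seed = 9,
                         tissues = paste0("T", 1:3), n_per_tissue = 2)
  cl <- classify_features(cpm_normalize(sim$counts), sim$groups)
  g <- glance(cl)
  expect_equal(g$n_features, 60)
  expect_equal(g$n_housekeeping + g$n_tissue_specific + g$n_neither, 60)
  expect_s3_class(tidy(cl), "tbl_df")
  expect_false(inherits(tidy(cl), "lnc_classification"))
  expect_s3_class(autoplot(cl), "ggplot")
})
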