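make_matrix <- function(counts, conditions = rep(c("A", "B"),
                                                 each = ncol(counts) / 2)) {
  km <- sprintf("K%05d", seq_len(nrow(counts)))  # lexicographically sorted ids
  kmer_count_matrix(km, counts,
                    data.frame(library_id = paste0("s", seq_len(ncol(counts))),
                               condition = conditions))
}

test_that("NFs are symmetric for identical columns and follow hand-computed ratios", {
  cnt <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2)
  m <- make_matrix(cnt)
  nf <- compute_nf(m, frac = 1)
  expect_equal(unname(nf), c(1, 1))
  # s2 = 2 x s1: ratios are 1/sqrt(2) and sqrt(2) after geometric-mean scaling
  cnt2 <- cbind(c(10L, 20L, 30L), c(20L, 40L, 60L))
  nf2 <- compute_nf(make_matrix(cnt2), frac = 1)
  expect_equal(unname(nf2), c(1 / sqrt(2), sqrt(2)))
  expect_equal(prod(nf2), 1)
})

test_that("NFs match a direct median-of-ratios oracle (and DESeq2) on random matrices", {
  set.seed(31)
  for (i in 1:20) {
    cnt <- matrix(rnbinom(50 * 4, mu = 50, size = 5) + 1L, 50, 4)
    m <- make_matrix(cnt, conditions = c("A", "A", "B", "B"))
    nf <- compute_nf(m, frac = 1)
    geo <- exp(rowMeans(log(cnt)))
    oracle <- apply(cnt / geo, 2, median)
    oracle <- oracle / exp(mean(log(oracle)))
    expect_equal(unname(nf), unname(oracle), tolerance = 1e-12)
  }
  # DESeq2's size factors as an independent reference (same convention:
  # both are median-of-ratios rescaled to geometric mean 1)
  skip_if_not_installed("DESeq2")
  cnt <- matrix(rnbinom(200 * 6, mu = 80, size = 5) + 1L, 200, 6)
  m <- make_matrix(cnt, conditions = rep(c("A", "B"), each = 3))
  nf <- compute_nf(m, frac = 1)
  sf <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  sf <- sf / exp(mean(log(sf)))
  # DESeq2 takes the median in log space: for an even row count the two
  # middle ratios are averaged geometrically rather than arithmetically,
  # hence agreement only to ~1e-4
  expect_equal(unname(nf), unname(sf), tolerance = 1e-3)
})

test_that("rows containing zeros are excluded from the NF pseudo-reference", {
  cnt <- rbind(c(10L, 20L), c(0L, 50L), c(30L, 60L))
  nf <- compute_nf(make_matrix(cnt), frac = 1)
  # only rows 1 and 3 (all positive) contribute; both give ratio 1:2
  expect_equal(unname(nf), c(1 / sqrt(2), sqrt(2)))
  all0 <- rbind(c(0L, 5L), c(0L, 7L))    # every row contains a zero
  expect_error(compute_nf(make_matrix(all0), frac = 1), "positive")
})

test_that("ttest_pvalue equals an independent Welch t implementation", {
  nf <- c(0.9, 1.1, 1, 1, 0.95, 1.05)
  groups <- rep(c("A", "B"), each = 3)
  set.seed(17)
  for (i in 1:100) {
    row <- rnbinom(6, mu = 40, size = 5)
    y <- log2(row / nf + 1)
    ref <- tryCatch(t.test(y[4:6], y[1:3])$p.value, error = function(e) NA)
    p <- ttest_pvalue(row, nf, groups)
    if (!is.na(ref)) expect_equal(p, ref, tolerance = 1e-9)
  }
  expect_equal(ttest_pvalue(c(5L, 5L, 5L, 5L, 5L, 5L), rep(1, 6), groups), 1)
  expect_equal(ttest_pvalue(rep(0L, 6), rep(1, 6), groups), 1)
  expect_error(ttest_pvalue(1:4, rep(1, 4), c("A", "B", "B", "B")),
               "at least 2")
})

test_that("ttest_pvalue is invariant to rescaling counts together with NFs", {
  set.seed(23)
  row <- rnbinom(12, mu = 60, size = 8)
  nf <- runif(12, 0.8, 1.25)
  groups <- rep(c("A", "B"), each = 6)
  p1 <- ttest_pvalue(row, nf, groups)
  p2 <- ttest_pvalue(row * 4L, nf * 4, groups)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("glm p-values are chunk-invariant and degenerate rows give p = 1", {
  sim <- simulate_count_rows(300, 20, seed = 5)
  nf <- rep(1, 12)
  p_all <- glm_chunk_pvalues(sim$counts, nf, sim$groups)
  p_split <- c(glm_chunk_pvalues(sim$counts[1:111, ], nf, sim$groups),
               glm_chunk_pvalues(sim$counts[112:320, ], nf, sim$groups))
  expect_equal(p_all, p_split, tolerance = 1e-12)
  flat <- matrix(7L, 2, 12)
  expect_equal(glm_chunk_pvalues(flat, nf, sim$groups), c(1, 1))
})

test_that("glm mode is calibrated under the null and beats the t-test in power", {
  nf <- rep(1, 12)
  null <- simulate_count_rows(8000, 0, seed = 19)
  p_g <- glm_chunk_pvalues(null$counts, nf, null$groups)
  expect_lt(mean(p_g < 0.05), 0.10)        # within 2x nominal
  p_t <- ttest_pvalue(null$counts, nf, null$groups)
  expect_lt(mean(p_t < 0.05), 0.10)
  # fold 4 at low counts: the count model is the more sensitive test
  pow <- simulate_count_rows(0, 1500, mean_range = c(4, 8),
                             dispersion = 0.3, fold = 4, seed = 29)
  pw_g <- mean(glm_chunk_pvalues(pow$counts, nf, pow$groups) < 0.05)
  pw_t <- mean(ttest_pvalue(pow$counts, nf, pow$groups) < 0.05)
  expect_gt(pw_g, pw_t)
})

test_that("bh_adjust reproduces the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent oracle: literal step-up with monotonicity enforcement
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); r <- numeric(m)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    r[o] <- pmin(q, 1)
    r
  }
  set.seed(37)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  p <- sort(runif(30))
  expect_false(is.unsorted(bh_adjust(p)))  # monotone on sorted input
})

test_that("de_filter thresholds on adjusted p and reports means and fold changes", {
  sim <- simulate_count_rows(500, 10, fold = 16, seed = 3)
  m <- make_matrix(sim$counts, conditions = sim$groups)
  nf <- compute_nf(m, frac = 1)
  all_rows <- de_filter(m, nf, method = "ttest", pvalue_threshold = 1)
  expect_equal(nrow(all_rows), 510L)       # threshold 1 returns everything
  expect_true(all(all_rows$padj >= all_rows$pvalue))
  hits <- de_filter(m, nf, method = "ttest", pvalue_threshold = 0.05)
  spiked_ids <- sprintf("K%05d", which(sim$is_spiked))
  expect_true(all(spiked_ids %in% hits$tag))     # 16-fold spikes all pass
  expect_true(all(hits[hits$tag %in% spiked_ids]$log2FC > 0))
  empty <- kmer_count_matrix(character(0), matrix(integer(0), 0, 12),
                             m$samples)
  expect_warning(none <- de_filter(empty, nf), "empty")
  expect_equal(nrow(none), 0L)
})
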