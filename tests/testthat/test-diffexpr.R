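# Normalization, the permutation DE engine, the filter cascade, and the
# restored-at-follow-up set logic.

named_matrix <- function(values, nrow, ncol) {
  matrix(values, nrow, ncol,
         dimnames = list(sprintf("g%03d", seq_len(nrow)),
                         sprintf("s%02d", seq_len(ncol))))
}

test_that("median-of-ratios factors satisfy the defining identities", {
  m <- named_matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(unname(scaling_factors(m)), rep(1, 3))

  m2 <- named_matrix(c(1:10, 2 * (1:10)), 10, 2)
  f <- scaling_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)

  # invariant under feature reordering
  perm <- sample(10)
  expect_equal(scaling_factors(m2[perm, ]), f)

  # scale-equivariant: scaling one sample by c scales its factor relative
  # to every other sample by c (the geometric-mean reference itself moves,
  # so only factor ratios are identifiable)
  m3 <- m2
  m3[, 1] <- m3[, 1] * 5
  f3 <- scaling_factors(m3)
  expect_equal(unname((f3[1] / f3[2]) / (f[1] / f[2])), 5)

  # undefined without an everywhere-positive feature
  bad <- named_matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(scaling_factors(bad), "nonzero")
})

test_that("median-of-ratios factors agree with an established implementation", {
  counts <- make_count_matrix(300L, c(5L, 5L),
                              planted_effects = stats::setNames(
                                rep(1.5, 20), sprintf("gene%04d", 1:20)),
                              seed = 42L)$matrix$counts
  ours <- scaling_factors(counts)
  # the reference implementation takes the median in log space, which can
  # differ at even feature counts where the two middle ratios are averaged
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("features with identical values in all samples get log2fc 0 and p 1", {
  m <- named_matrix(rep(c(10, 55, 200, 7), 4), 4, 4)
  mat <- count_matrix(m, "lnRNA",
                      stats::setNames(rep(c("A", "B"), each = 2),
                                      colnames(m)))
  calls <- de_test(mat, seed = 1L)
  expect_equal(calls$log2fc, rep(0, 4))
  expect_equal(calls$p, rep(1, 4))
  expect_identical(calls$direction, rep("none", 4))
})

test_that("group labels drive the permutation engine, exact for small designs", {
  # 2 vs 2: all 6 label choices enumerated, p has resolution 1/6
  m <- named_matrix(c(10, 100, 11, 101, 50, 500, 52, 505), 2, 4)
  mat <- count_matrix(m, "lnRNA",
                      stats::setNames(c("A", "A", "B", "B"), colnames(m)))
  calls <- de_test(mat, seed = 1L)
  expect_true(all(calls$p * 6 == round(calls$p * 6)))
  expect_error(de_test(count_matrix(m[, 1:3], "lnRNA",
                                    stats::setNames(c("A", "A", "B"),
                                                    colnames(m)[1:3]))),
               "at least 2")
})

test_that("the engine recovers planted effects and controls the null FDR", {
  eff <- stats::setNames(rep(2, 30), sprintf("gene%04d", 1:30))
  sim <- make_count_matrix(800L, c(10L, 10L), eff, 200, 0.1, "lnRNA",
                           seed = 13L)
  calls <- apply_filter_cascade(de_test(sim$matrix, seed = 14L), "lnRNA")
  planted <- calls[calls$feature %in% names(eff), ]
  expect_gte(mean(planted$fdr <= 0.05 & abs(planted$log2fc - 2) <= 0.5),
             0.9)
  expect_true(all(planted$direction[planted$significant] == "up"))

  null_calls <- calls[!calls$feature %in% names(eff), ]
  expect_lte(mean(null_calls$fdr <= 0.05), 0.02)
})

test_that("the filter cascade applies the class thresholds with the printed strictness", {
  mk <- function(fdr, mean_count, log2fc) {
    data.frame(feature = "f", mean_count = mean_count, log2fc = log2fc,
               p = fdr, fdr = fdr, direction = "up", significant = FALSE,
               stringsAsFactors = FALSE)
  }
  expect_true(apply_filter_cascade(mk(0.01, 60, 1.2), "lnRNA")$significant)
  # FDR boundary is non-strict
  expect_true(apply_filter_cascade(mk(0.05, 60, 1.2), "lnRNA")$significant)
  # mean and fold-change boundaries are strict
  expect_false(apply_filter_cascade(mk(0.01, 50, 1.2), "lnRNA")$significant)
  expect_false(apply_filter_cascade(mk(0.01, 60, 1), "lnRNA")$significant)
  expect_true(apply_filter_cascade(mk(0.01, 21, 0.586), "sRNA")$significant)
  expect_false(apply_filter_cascade(mk(0.01, 21, 0.585), "sRNA")$significant)
  expect_false(apply_filter_cascade(mk(0.01, 20, 0.6), "sRNA")$significant)
  # down-regulation passes on |log2fc|
  expect_true(apply_filter_cascade(mk(0.01, 60, -1.2), "lnRNA")$significant)
  # idempotent
  once <- apply_filter_cascade(mk(0.01, 60, 1.2), "lnRNA")
  expect_identical(apply_filter_cascade(once, "lnRNA"), once)
  expect_error(apply_filter_cascade(mk(0.01, 60, 1.2), "circRNA"), "arg")
})

test_that("BH adjustment matches the explicit step-up formula", {
  set.seed(5)
  p <- runif(40)^2
  expect_equal(adjust_pvalues(p, "BH"), oracle_bh(p))
  # monotone non-decreasing in p-value rank
  expect_true(all(diff(adjust_pvalues(sort(p), "BH")) >= -1e-12))
})

test_that("restored features are the significant-at-baseline-only set, with direction", {
  mk <- function(features, directions, sig) {
    data.frame(feature = features, mean_count = 100,
               log2fc = ifelse(directions == "up", 2, -2), p = 0.001,
               fdr = 0.001, direction = directions, significant = sig,
               stringsAsFactors = FALSE)
  }
  t0 <- mk(c("g1", "g2"), c("up", "down"), c(TRUE, TRUE))
  t10 <- mk(c("g1", "g2"), c("up", "down"), c(FALSE, TRUE))
  r <- restored_features(t0, t10)
  expect_identical(r$feature, "g1")
  expect_identical(r$direction, "up")

  # absent at follow-up counts as restored
  r2 <- restored_features(t0, t10[t10$feature == "g2", ])
  expect_identical(r2$feature, "g1")

  expect_identical(nrow(restored_features(t0, t0)), 0L)
  empty_t0 <- mk("g1", "up", FALSE)
  expect_identical(nrow(restored_features(empty_t0, t10)), 0L)

  # a gene up at baseline (log2fc 1.91, fdr 2.3e-17) and non-significant at
  # follow-up is returned with its baseline attributes
  t0b <- data.frame(feature = "ZNF628", mean_count = 500, log2fc = 1.91,
                    p = 1e-18, fdr = 2.3e-17, direction = "up",
                    significant = TRUE, stringsAsFactors = FALSE)
  t10b <- data.frame(feature = "ZNF628", mean_count = 450, log2fc = 0.4,
                     p = 0.3, fdr = 0.6, direction = "up",
                     significant = FALSE, stringsAsFactors = FALSE)
  rb <- restored_features(t0b, t10b)
  expect_identical(rb$feature, "ZNF628")
  expect_equal(rb$log2fc_t0, 1.91)
  expect_equal(rb$fdr_t0, 2.3e-17)
})
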