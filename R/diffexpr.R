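# Normalization, the permutation DE engine, the significance filter cascade,
# and the restored-at-follow-up set logic.

#' Median-of-ratios scaling factors
#'
#' Library-size factors in the median-of-ratios style used by model-based DE
#' tools: the per-feature reference is the geometric mean across samples
#' over features positive in every sample; a sample's factor is the median
#' of its counts over those references. Factors are invariant under feature
#' reordering and scale-equivariant (multiplying a sample's counts by c
#' multiplies its factor by c).
#'
#' @param mat a `count_matrix`, or a plain counts matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
scaling_factors <- function(mat) {
  counts <- if (inherits(mat, "count_matrix")) mat$counts else mat
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no feature has nonzero counts in every sample; ",
         "median-of-ratios factors are undefined")
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- exp(rowMeans(logc))
  apply(counts[pos, , drop = FALSE], 2L, function(col) {
    stats::median(col / ref)
  })
}

#' Permutation test for differential expression
#'
#' A fully specified substitute for an empirical-Bayes DE engine: counts are
#' normalized by median-of-ratios factors, the per-feature statistic is the
#' difference in group means of log2(normalized count + 0.5), and its
#' two-sided p-value comes from permuting group labels — all distinct label
#' assignments when there are at most `max_exact` of them, otherwise
#' `n_perm` Monte-Carlo permutations with `p = (b + 1) / (m + 1)`. FDR is
#' Benjamini-Hochberg across features. The reported `log2fc` is
#' `log2((mean_B + 0.5) / (mean_A + 0.5))` of normalized counts, and
#' `mean_count` is the raw mean across all samples of the comparison.
#'
#' @param mat a `count_matrix` with >= 2 samples per group.
#' @param seed integer seed for the Monte-Carlo permutations.
#' @param n_perm Monte-Carlo permutation count (default 2000; resolution
#'   5e-4 suffices for a 0.05 significance gate).
#' @param max_exact enumerate all label assignments when their number is at
#'   most this (default 2000).
#' @return data frame (`de_calls`): `feature`, `mean_count`, `log2fc`, `p`,
#'   `fdr`, `direction` (`up`/`down`/`none` by the sign of `log2fc`),
#'   `significant` (all `FALSE` until [apply_filter_cascade()]).
#' @export
de_test <- function(mat, seed = 1L, n_perm = 2000L, max_exact = 2000L) {
  stopifnot(inherits(mat, "count_matrix"))
  counts <- mat$counts
  groups <- mat$groups
  nA <- sum(groups == "A"); nB <- sum(groups == "B")
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 samples")
  n <- nA + nB

  f <- scaling_factors(mat)
  q <- sweep(counts, 2L, f, "/")
  L <- log2(q + 0.5)
  idx_b <- which(groups == "B")

  mean_a <- rowMeans(q[, groups == "A", drop = FALSE])
  mean_b <- rowMeans(q[, idx_b, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  # weights so that L %*% w = mean over B-labelled minus mean over
  # A-labelled samples
  stat_weights <- function(b_idx) {
    w <- rep(-1 / nA, n)
    w[b_idx] <- 1 / nB
    w
  }
  obs <- as.numeric(L %*% stat_weights(idx_b))

  n_exact <- choose(n, nB)
  if (n_exact <= max_exact) {
    combs <- utils::combn(n, nB)
    W <- apply(combs, 2L, stat_weights)
    null_stats <- L %*% W
    p <- rowMeans(abs(null_stats) >= abs(obs) - 1e-12)
  } else {
    W <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) stat_weights(sample.int(n, nB)),
             numeric(n))
    })
    null_stats <- L %*% W
    b <- rowSums(abs(null_stats) >= abs(obs) - 1e-12)
    p <- (b + 1) / (n_perm + 1)
  }

  data.frame(
    feature = rownames(counts),
    mean_count = rowMeans(counts),
    log2fc = log2fc,
    p = p,
    fdr = stats::p.adjust(p, method = "BH"),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none")),
    significant = FALSE,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Significance filter cascade
#'
#' Marks a feature significant when all three study filters hold:
#' FDR <= `fdr_max` (non-strict), raw mean count strictly above the
#' class threshold (50 for lnRNA, 20 for sRNA), and absolute log2 fold
#' change strictly above the class threshold (1 for lnRNA, i.e. doubling;
#' 0.585 for sRNA, i.e. an increase by one and a half times). Idempotent; it
#' depends only on (`fdr`, `mean_count`, `log2fc`, class).
#'
#' @param calls a `de_calls` data frame from [de_test()].
#' @param feature_class `"lnRNA"` or `"sRNA"`.
#' @param fdr_max,mean_min,lfc_min override the class defaults.
#' @return `calls` with `significant` set.
#' @export
apply_filter_cascade <- function(calls, feature_class = c("lnRNA", "sRNA"),
                                 fdr_max = 0.05,
                                 mean_min = NULL, lfc_min = NULL) {
  feature_class <- match.arg(feature_class)
  if (is.null(mean_min)) {
    mean_min <- if (feature_class == "lnRNA") 50 else 20
  }
  if (is.null(lfc_min)) {
    lfc_min <- if (feature_class == "lnRNA") 1 else 0.585
  }
  calls$significant <- calls$fdr <= fdr_max &
    calls$mean_count > mean_min &
    abs(calls$log2fc) > lfc_min
  calls
}

#' Features no longer differentially expressed at follow-up
#'
#' Set logic for the "restored under treatment" comparison: features
#' significant in the baseline-vs-control contrast that are not significant
#' (or absent) in the follow-up-vs-control contrast, keeping their baseline
#' direction.
#'
#' @param calls_t0_vs_hc,calls_t10_vs_hc filtered `de_calls` data frames
#'   (after [apply_filter_cascade()]).
#' @return data frame `feature`, `direction` (baseline direction),
#'   `log2fc_t0`, `fdr_t0`.
#' @export
restored_features <- function(calls_t0_vs_hc, calls_t10_vs_hc) {
  sig_t0 <- calls_t0_vs_hc[calls_t0_vs_hc$significant, , drop = FALSE]
  sig_t10 <- calls_t10_vs_hc$feature[calls_t10_vs_hc$significant]
  restored <- sig_t0[!(sig_t0$feature %in% sig_t10), , drop = FALSE]
  data.frame(
    feature = restored$feature,
    direction = restored$direction,
    log2fc_t0 = restored$log2fc,
    fdr_t0 = restored$fdr,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
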