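# Exact paired one-tailed Wilcoxon signed-rank test, Fisher-exact gene-set
# enrichment, and multiple-testing corrections.

#' Exact one-tailed paired Wilcoxon signed-rank test
#'
#' Computes differences `d = t10 - t0`, drops zero differences (the
#' standard signed-rank convention), ranks `|d|` with mid-ranks for ties,
#' and obtains the exact one-sided tail probability of the positive-rank
#' sum by enumerating all `2^n` sign assignments (as subset sums of the
#' observed ranks, so the result is exact conditional on the observed rank
#' multiset even with ties). `alternative = "greater"` tests for an
#' increase (t10 > t0).
#'
#' @param t0,t10 paired numeric vectors of equal length.
#' @param alternative `"greater"` (evidence t10 > t0) or `"less"`.
#' @return a `wilcoxon_result`: `n_used`, `w_plus`, `w_minus`,
#'   `p_one_sided`, `alternative`.
#' @export
exact_wilcoxon_one_tailed <- function(t0, t10,
                                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(t0) != length(t10)) stop("t0 and t10 must have equal length")
  d <- t10 - t0
  d <- d[d != 0]
  n_used <- length(d)
  if (n_used == 0L) {
    stop(structure(
      class = c("smaseq_degenerate_error", "error", "condition"),
      list(message = "all paired differences are zero; test degenerate",
           call = sys.call(-1))
    ))
  }
  if (n_used > 20L) {
    stop("n_used > 20: exact enumeration not attempted; ",
         "use a normal approximation instead")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])

  # all 2^n subset sums of the ranks = the exact null distribution of W+
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  p <- if (alternative == "greater") {
    mean(sums >= w_plus - 1e-9)
  } else {
    mean(sums <= w_plus + 1e-9)
  }
  structure(
    list(n_used = n_used, w_plus = w_plus, w_minus = w_minus,
         p_one_sided = p, alternative = alternative),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("exact one-sided Wilcoxon signed-rank test (", x$alternative, ")\n",
      "n (nonzero) = ", x$n_used, ", W+ = ", x$w_plus, ", W- = ", x$w_minus,
      "\np = ", format(x$p_one_sided, digits = 10),
      " (quoted to 3 decimals: ", sprintf("%.3f", truncate_p3(x$p_one_sided)),
      ")\n", sep = "")
  invisible(x)
}

#' Fisher-exact gene-set enrichment
#'
#' One-sided (enrichment) hypergeometric upper-tail test per term, with
#' Benjamini-Hochberg and Bonferroni corrections across the tested terms.
#' Gene sets are intersected with the universe; terms with no member in the
#' universe are skipped.
#'
#' @param query character vector of query ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data frame per tested term: `term`, `k` (query hits), `K` (term
#'   size in universe), `n` (query size), `N` (universe size), `p`, `p_bh`,
#'   `p_bonferroni`.
#' @export
fisher_enrichment <- function(query, universe, gene_sets) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_bh = numeric(0), p_bonferroni = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$p_bh <- adjust_pvalues(out$p, "BH")
  out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni")
  rownames(out) <- NULL
  out[order(out$p, out$term), ]
}

#' Multiple-testing correction
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (Benjamini-Hochberg step-up) or `"bonferroni"`
#'   (`min(1, m * p)`).
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
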