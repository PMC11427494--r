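# Inverse-expression miRNA-target integration: underexpressed genes are
# evaluated as targets of overexpressed miRNAs, and overexpressed genes as
# targets of underexpressed miRNAs, then each candidate pair is kept only
# with interaction-database support and labelled validated or predicted.

#' Inversely expressed miRNA-gene candidate pairs
#'
#' Crosses significant miRNAs with significant genes of the opposite
#' direction: (miRNA up, gene down) and (miRNA down, gene up). Pairs with
#' the same direction are never emitted.
#'
#' @param mirna_calls,gene_calls filtered `de_calls` data frames carrying
#'   `direction` and `significant`.
#' @return data frame `mirna`, `mirna_direction`, `gene`, `gene_direction`.
#' @export
inverse_candidate_pairs <- function(mirna_calls, gene_calls) {
  for (d in list(mirna_calls, gene_calls)) {
    if (!all(c("direction", "significant") %in% names(d))) {
      stop("calls must carry 'direction' and 'significant' columns")
    }
  }
  m <- mirna_calls[mirna_calls$significant &
                     mirna_calls$direction %in% c("up", "down"), ]
  g <- gene_calls[gene_calls$significant &
                    gene_calls$direction %in% c("up", "down"), ]
  cross <- function(mm, gg) {
    if (nrow(mm) == 0L || nrow(gg) == 0L) return(NULL)
    out <- expand.grid(mi = seq_len(nrow(mm)), gi = seq_len(nrow(gg)),
                       KEEP.OUT.ATTRS = FALSE)
    data.frame(
      mirna = mm$feature[out$mi],
      mirna_direction = mm$direction[out$mi],
      gene = gg$feature[out$gi],
      gene_direction = gg$direction[out$gi],
      stringsAsFactors = FALSE
    )
  }
  res <- rbind(
    cross(m[m$direction == "up", ], g[g$direction == "down", ]),
    cross(m[m$direction == "down", ], g[g$direction == "up", ])
  )
  if (is.null(res)) {
    res <- data.frame(mirna = character(0), mirna_direction = character(0),
                      gene = character(0), gene_direction = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Annotate candidate pairs against an interaction database
#'
#' A candidate pair is retained when it is supported by an experimentally
#' validated record, or by at least `min_predictors` distinct prediction
#' algorithms. Validated support dominates: the pair is labelled
#' `validated` whenever any validated record exists, `predicted` otherwise.
#' Unsupported pairs are dropped.
#'
#' @param pairs output of [inverse_candidate_pairs()].
#' @param db an `interaction_db` data frame (`mirna`, `gene`, `source` with
#'   `source` either `"validated"` or `"predicted:<algorithm>"`).
#' @param min_predictors minimum number of distinct predictors for a
#'   predicted-only pair (default 1; the study does not state a consensus
#'   threshold).
#' @return integration table: `pairs` columns plus `label`
#'   (`validated`/`predicted`), `n_predictors`, `supporting_sources`
#'   (semicolon-joined).
#' @export
annotate_pairs <- function(pairs, db, min_predictors = 1L) {
  stopifnot(min_predictors >= 1L)
  if (nrow(pairs) == 0L) {
    return(cbind(pairs,
                 data.frame(label = character(0), n_predictors = integer(0),
                            supporting_sources = character(0),
                            stringsAsFactors = FALSE)))
  }
  key <- function(m, g) paste(m, g, sep = "\r")
  db_key <- key(db$mirna, db$gene)
  pair_key <- key(pairs$mirna, pairs$gene)

  label <- character(nrow(pairs))
  n_pred <- integer(nrow(pairs))
  sources <- character(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    src <- sort(unique(db$source[db_key == pair_key[i]]))
    validated <- "validated" %in% src
    preds <- src[startsWith(src, "predicted:")]
    n_pred[i] <- length(preds)
    if (validated) {
      keep[i] <- TRUE
      label[i] <- "validated"
    } else if (length(preds) >= min_predictors) {
      keep[i] <- TRUE
      label[i] <- "predicted"
    }
    sources[i] <- paste(src, collapse = ";")
  }
  out <- pairs[keep, , drop = FALSE]
  out$label <- label[keep]
  out$n_predictors <- n_pred[keep]
  out$supporting_sources <- sources[keep]
  rownames(out) <- NULL
  out
}
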