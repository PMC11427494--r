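# Independent oracles used across the suite. These deliberately avoid the
# code paths of the implementation: motif counting by positional substring
# comparison (no pattern-matching library), graph metrics by exhaustive
# clique enumeration / BFS / explicit shortest-path listing on adjacency
# matrices, hypergeometric tails by binomial-coefficient sums.

## ---- naive positional motif scan ---------------------------------------

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

# does `pattern` occur in each sequence? checked offset by offset
oracle_occurs <- function(seqs, pattern) {
  k <- nchar(pattern)
  L <- nchar(seqs[1])
  hit <- rep(FALSE, length(seqs))
  for (off in seq_len(L - k + 1L)) {
    hit <- hit | substr(seqs, off, off + k - 1L) == pattern
  }
  hit
}

oracle_fragment_match <- function(seqs1, seqs2, pattern, revcomp) {
  hit <- oracle_occurs(seqs1, pattern) | oracle_occurs(seqs2, pattern)
  if (revcomp) {
    rc <- oracle_revcomp(pattern)
    hit <- hit | oracle_occurs(seqs1, rc) | oracle_occurs(seqs2, rc)
  }
  hit
}

# per-motif fragment tallies, mirroring the counting contract: single (and
# junction-concatenated) motifs match in either mate; paired motifs need
# both subsequences in the fragment (opposite mates if paired_strict)
oracle_motif_tally <- function(reads, catalog, paired_strict = FALSE) {
  revcomp <- isTRUE(attr(catalog, "revcomp"))
  out <- integer(nrow(catalog))
  names(out) <- catalog$name
  if (length(reads$ids) == 0L) return(out)
  for (i in seq_len(nrow(catalog))) {
    row <- catalog[i, ]
    if (isTRUE(row$paired)) {
      p1m1 <- oracle_fragment_match(reads$mate1, reads$mate1, row$part1,
                                    revcomp)
      p1m2 <- oracle_fragment_match(reads$mate2, reads$mate2, row$part1,
                                    revcomp)
      p2m1 <- oracle_fragment_match(reads$mate1, reads$mate1, row$part2,
                                    revcomp)
      p2m2 <- oracle_fragment_match(reads$mate2, reads$mate2, row$part2,
                                    revcomp)
      out[i] <- if (paired_strict) {
        sum((p1m1 & p2m2) | (p1m2 & p2m1))
      } else {
        sum((p1m1 | p1m2) & (p2m1 | p2m2))
      }
    } else {
      pat <- paste0(row$part1, ifelse(is.na(row$part2), "", row$part2))
      out[i] <- sum(oracle_fragment_match(reads$mate1, reads$mate2, pat,
                                          revcomp))
    }
  }
  out
}

## ---- brute-force graph metrics on an adjacency matrix ------------------

ig_to_adj <- function(g) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1], el[i, 2]] <- 1L
    A[el[i, 2], el[i, 1]] <- 1L
  }
  A
}

brute_bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] == 1L)
    new <- nb[is.infinite(d[nb])]
    d[new] <- d[v] + 1
    queue <- c(queue, new)
  }
  d
}

brute_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    comp[is.finite(brute_bfs_dist(A, s))] <- cid
  }
  comp
}

# all maximal cliques by subset enumeration (n <= ~12)
brute_max_cliques <- function(A) {
  n <- nrow(A)
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    vs <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(vs) == 0L) next
    sub <- A[vs, vs, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0L)) next
    outside <- setdiff(seq_len(n), vs)
    extensible <- any(vapply(outside, function(u) all(A[u, vs] == 1L),
                             logical(1)))
    if (!extensible) cliques[[length(cliques) + 1L]] <- vs
  }
  cliques
}

# every shortest s->t path as a vertex list, via backward DFS on distances
brute_all_shortest_paths <- function(A, d_s, t, s) {
  if (t == s) return(list(s))
  if (is.infinite(d_s[t])) return(list())
  preds <- which(A[t, ] == 1L & d_s == d_s[t] - 1)
  out <- list()
  for (u in preds) {
    for (p in brute_all_shortest_paths(A, d_s, u, s)) {
      out[[length(out) + 1L]] <- c(p, t)
    }
  }
  out
}

brute_hub_metrics <- function(A, dmnc_exponent = 1.7) {
  n <- nrow(A)
  nodes <- rownames(A)
  deg <- rowSums(A)

  mcc <- numeric(n)
  for (cl in brute_max_cliques(A)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }

  dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) <= 1L) next
    sub <- A[nb, nb, drop = FALSE]
    comp <- brute_components(sub)
    sizes <- tabulate(comp)
    if (max(sizes) <= 1L) next
    cand <- which(sizes == max(sizes))
    # same deterministic tie-break as the implementation: most edges, then
    # the component holding the smallest node id
    pick <- cand[1]
    if (length(cand) > 1L) {
      ec <- vapply(cand, function(ci) {
        vs <- which(comp == ci)
        sum(sub[vs, vs]) / 2
      }, numeric(1))
      first_id <- vapply(cand, function(ci) {
        min(rownames(sub)[comp == ci])
      }, character(1))
      pick <- cand[order(-ec, first_id)[1]]
    }
    vs <- which(comp == pick)
    dmnc[v] <- (sum(sub[vs, vs]) / 2) / length(vs)^dmnc_exponent
  }

  D <- t(vapply(seq_len(n), function(s) brute_bfs_dist(A, s), numeric(n)))

  closeness <- vapply(seq_len(n), function(v) {
    sum(1 / D[v, -v][is.finite(D[v, -v])])
  }, numeric(1))

  comp <- brute_components(A)
  radiality <- numeric(n)
  for (ci in unique(comp)) {
    vs <- which(comp == ci)
    nc <- length(vs)
    if (nc == 1L) next
    dc <- D[vs, vs, drop = FALSE]
    diam <- max(dc)
    for (i in seq_along(vs)) {
      radiality[vs[i]] <- sum(diam + 1 - dc[i, -i]) / (nc - 1)
    }
  }

  bottleneck <- numeric(n)
  for (s in seq_len(n)) {
    vs <- which(comp == comp[s])
    nc <- length(vs)
    if (nc == 1L) next
    ds <- D[s, ]
    parent <- rep(NA_integer_, n)
    for (v in vs) {
      if (v == s) next
      cand <- which(A[v, ] == 1L & ds == ds[v] - 1)
      parent[v] <- cand[order(nodes[cand])[1]]
    }
    desc <- integer(n)
    for (v in vs[order(-ds[vs])]) {
      if (v == s) next
      desc[parent[v]] <- desc[parent[v]] + desc[v] + 1L
    }
    for (v in vs) {
      if (v != s && desc[v] > nc / 4) bottleneck[v] <- bottleneck[v] + 1
    }
  }

  betweenness <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        paths <- brute_all_shortest_paths(A, D[s, ], t, s)
        if (length(paths) == 0L) next
        for (p in paths) {
          interior <- setdiff(p, c(s, t))
          betweenness[interior] <- betweenness[interior] + 1 / length(paths)
        }
      }
    }
  }

  clustering <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2L) return(0)
    nb <- which(A[v, ] == 1L)
    tri <- sum(A[nb, nb]) / 2
    2 * tri / (deg[v] * (deg[v] - 1))
  }, numeric(1))

  data.frame(node = nodes, degree = as.integer(deg), mcc = mcc, dmnc = dmnc,
             closeness = closeness, radiality = radiality,
             bottleneck = bottleneck, betweenness = betweenness,
             clustering = clustering, row.names = NULL,
             stringsAsFactors = FALSE)
}

expect_metrics_match <- function(g, tol = 1e-10) {
  got <- hub_metrics(g)
  want <- brute_hub_metrics(ig_to_adj(g))
  expect_equal(got, want, tolerance = tol)
}

# one representative igraph per isomorphism class of all graphs on
# exactly n nodes, n = 1..max_n (computed once per test run)
graph_iso_reps <- local({
  cache <- list()
  function(max_n) {
    key <- as.character(max_n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    seen <- new.env(parent = emptyenv())
    reps <- list()
    for (n in seq_len(max_n)) {
      pairs <- if (n >= 2) t(utils::combn(n, 2L)) else matrix(0L, 0, 2)
      ne <- nrow(pairs)
      for (mask in seq_len(2^ne) - 1L) {
        sel <- bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0L
        g <- igraph::make_empty_graph(n, directed = FALSE)
        if (any(sel)) g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
        cp <- igraph::canonical_permutation(g)$labeling
        gc <- igraph::permute(g, cp)
        el <- igraph::as_edgelist(gc)
        canon <- paste(n, paste(el[order(el[, 1], el[, 2]), ],
                                collapse = ","), sep = "|")
        if (is.null(seen[[canon]])) {
          assign(canon, TRUE, envir = seen)
          igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
          reps[[length(reps) + 1L]] <- g
        }
      }
    }
    cache[[key]] <<- reps
    reps
  }
})

random_named_gnp <- function(n, p, seed) {
  g <- smaseq:::with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

## ---- misc ---------------------------------------------------------------

# hypergeometric upper tail by explicit binomial-coefficient sum
oracle_hyper_upper <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# BH step-up by the explicit formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
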