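# Molecular-graph construction (PPI + miRNA-gene edges) and the eight hub
# centrality metrics used for hub-gene ranking. Definitions are fixed,
# deterministic and component-safe:
#   degree(v)      |N(v)|
#   MCC(v)         sum over maximal cliques C containing v of (|C|-1)!,
#                  with MCC(isolated) = 1 (its size-1 maximal clique)
#   DMNC(v)        |E(MNC)| / |V(MNC)|^eps, MNC = largest connected
#                  component of the subgraph induced on N(v); 0 if |V| <= 1
#   closeness(v)   sum over w != v of 1/d(v, w), with 1/Inf = 0
#   radiality(v)   sum over w reachable from v of
#                  (diam_c + 1 - d(v, w)) / (n_c - 1), within v's component
#   bottleneck(v)  number of roots s != v whose deterministic BFS
#                  shortest-path tree gives v strictly more than n_c / 4
#                  strict descendants
#   betweenness(v) unnormalized shortest-path betweenness
#   clustering(v)  2 tri(v) / (deg(v) (deg(v) - 1)), 0 when deg < 2

#' Build the molecular graph from PPI and miRNA-gene edge lists
#'
#' Takes the union of the two edge sets as a simple undirected graph:
#' duplicate edges are collapsed and self-loops dropped with a warning.
#' Nodes appearing in the first column of `mirna_gene_edges` are marked
#' `kind = "miRNA"`, all others `"gene"`.
#'
#' @param ppi_edges data frame (or matrix) whose first two columns name the
#'   endpoints of protein-protein edges.
#' @param mirna_gene_edges optional data frame of (miRNA, gene) edges.
#' @return an undirected simple `igraph` graph with vertex attribute `kind`.
#' @export
build_graph <- function(ppi_edges, mirna_gene_edges = NULL) {
  as_edge_df <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (ncol(x) < 2L) stop("malformed ", what, " edge rows: need 2 columns")
    d <- data.frame(from = as.character(x[[1]]), to = as.character(x[[2]]),
                    stringsAsFactors = FALSE)
    if (anyNA(d$from) || anyNA(d$to) || any(d$from == "") || any(d$to == "")) {
      stop("malformed ", what, " edge rows: empty endpoint")
    }
    d
  }
  edges <- rbind(as_edge_df(ppi_edges, "PPI"),
                 as_edge_df(mirna_gene_edges, "miRNA-gene"))
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop edge(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  mirna_ids <- if (!is.null(mirna_gene_edges)) {
    unique(as.character(as.data.frame(mirna_gene_edges)[[1]]))
  } else character(0)
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% mirna_ids,
                              "miRNA", "gene")
  g
}

#' Compute the eight hub centrality metrics for every node
#'
#' @param net a non-empty undirected simple `igraph` graph (named vertices).
#' @param dmnc_exponent the DMNC density exponent (default 1.7).
#' @return data frame with one row per node: `node`, `degree`, `mcc`,
#'   `dmnc`, `closeness`, `radiality`, `bottleneck`, `betweenness`,
#'   `clustering`.
#' @export
hub_metrics <- function(net, dmnc_exponent = 1.7) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty graph")
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(n))
  }
  nodes <- igraph::V(net)$name

  deg <- igraph::degree(net)

  # MCC from the maximal-clique decomposition (isolated vertices are their
  # own size-1 maximal cliques, contributing 0! = 1)
  mcc <- stats::setNames(numeric(n), nodes)
  for (cl in igraph::max_cliques(net, min = 1L)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }

  dmnc <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(net, v))
    if (length(nb) <= 1L) return(0)
    sub <- igraph::induced_subgraph(net, nb)
    comp <- igraph::components(sub)
    if (max(comp$csize) <= 1L) return(0)
    # deterministic tie-break among equally large components: most edges,
    # then the one holding the lexicographically smallest node id
    cand <- which(comp$csize == max(comp$csize))
    pick <- cand[1]
    if (length(cand) > 1L) {
      stats_c <- t(vapply(cand, function(ci) {
        vs <- which(comp$membership == ci)
        c(igraph::ecount(igraph::induced_subgraph(sub, vs)),
          -match(min(igraph::V(sub)$name[vs]), sort(igraph::V(sub)$name)))
      }, numeric(2)))
      pick <- cand[order(-stats_c[, 1], -stats_c[, 2])[1]]
    }
    vs <- which(comp$membership == pick)
    mnc <- igraph::induced_subgraph(sub, vs)
    igraph::ecount(mnc) / igraph::vcount(mnc)^dmnc_exponent
  }, numeric(1))

  closeness <- igraph::harmonic_centrality(net, normalized = FALSE)

  comp <- igraph::components(net)
  d <- igraph::distances(net)
  radiality <- numeric(n)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    nc <- length(vs)
    if (nc == 1L) next
    dc <- d[vs, vs, drop = FALSE]
    diam <- max(dc)
    radiality[vs] <- (rowSums(diam + 1 - dc) - (diam + 1)) / (nc - 1)
  }

  bottleneck <- bottleneck_scores(net, comp)

  betweenness <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)

  clustering <- igraph::transitivity(net, type = "local", isolates = "zero")

  data.frame(
    node = nodes,
    degree = as.integer(deg),
    mcc = unname(mcc),
    dmnc = dmnc,
    closeness = unname(closeness),
    radiality = radiality,
    bottleneck = bottleneck,
    betweenness = unname(betweenness),
    clustering = clustering,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Bottleneck: for each root s, build the BFS shortest-path tree with
# lexicographic parent tie-breaking (each non-root node's parent is its
# smallest-named neighbor one step closer to the root), count strict
# descendants, and credit every node v != s whose descendant count strictly
# exceeds a quarter of the root's component size.
bottleneck_scores <- function(net, comp = igraph::components(net)) {
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net)
  adj <- lapply(adj, function(x) {
    x <- as.integer(x)
    x[order(nodes[x])]
  })
  scores <- numeric(n)
  d <- igraph::distances(net)
  for (s in seq_len(n)) {
    vs <- which(comp$membership == comp$membership[s])
    nc <- length(vs)
    if (nc == 1L) next
    ds <- d[s, ]
    parent <- rep(NA_integer_, n)
    for (v in vs) {
      if (v == s) next
      nb <- adj[[v]]
      parent[v] <- nb[which(ds[nb] == ds[v] - 1)[1]]
    }
    desc <- integer(n)
    for (v in vs[order(-ds[vs])]) {
      if (v == s) next
      desc[parent[v]] <- desc[parent[v]] + desc[v] + 1L
    }
    hit <- vs[vs != s & desc[vs] > nc / 4]
    scores[hit] <- scores[hit] + 1
  }
  scores
}

#' Rank nodes by a hub metric
#'
#' Deterministic ordering: descending by the metric, ties broken by degree
#' (descending) then node id (lexicographic ascending).
#'
#' @param scores data frame from [hub_metrics()].
#' @param metric one of `degree`, `mcc`, `dmnc`, `closeness`, `radiality`,
#'   `bottleneck`, `betweenness`, `clustering`.
#' @param k number of top nodes to return (the full ordering if `k` exceeds
#'   the node count).
#' @return `scores` rows in rank order with a `rank` column, first `k` rows.
#' @export
rank_hubs <- function(scores, metric = "mcc", k = 10L) {
  metrics <- c("degree", "mcc", "dmnc", "closeness", "radiality",
               "bottleneck", "betweenness", "clustering")
  if (!metric %in% metrics) {
    stop("unknown metric '", metric, "'; choose one of: ",
         paste(metrics, collapse = ", "))
  }
  stopifnot(k >= 1L)
  ord <- order(-scores[[metric]], -scores$degree, scores$node)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, k)
}
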