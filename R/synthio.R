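# Synthetic data generators: every input the pipeline needs, with known
# ground truth, so downstream stages are testable without any external data.

#' Simulate paired-end fragments carrying SMN1/SMN2 exon-7 motifs
#'
#' Generates 2 x `read_length` bp paired-end fragments in which each fragment
#' embeds, at a uniformly random offset inside i.i.d. uniform-ACGT flanks,
#' either one exon-7-bearing pattern (exon-7 start, exon6-exon7 junction,
#' exon7-exon8 junction, or the paired both-junction pattern split across the
#' two mates) or pure background. With genotype `"sma"` the gene of origin is
#' always SMN2 (SMN1 is deleted); with `"control"` SMN1 and SMN2 are drawn
#' with equal probability. Planted truth counts are tallied post hoc by
#' re-scanning the emitted reads (a naive base-R substring scan), not from
#' the draw plan, so accidental motif collisions in random flanks are part of
#' the truth.
#'
#' @param genotype `"control"` or `"sma"`.
#' @param n_fragments number of fragments (>= 0).
#' @param inclusion_rate probability in `[0, 1]` that a fragment carries an
#'   exon-7-bearing pattern.
#' @param read_length mate length in nt (>= 20).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param strand `"sense"` plants catalog patterns as written; `"antisense"`
#'   plants their reverse complements (library strandedness is a free
#'   parameter of the design, not an assertion).
#' @param both_junction_same_mate if `TRUE`, the two subsequences of the
#'   both-junction pattern are planted in the same mate instead of opposite
#'   mates (a stress fixture; the default follows the paired-end convention).
#' @return a list with `reads` (a `read_pair_set`) and `truth` (a
#'   `smn_truth`: genotype, inclusion rate, per-motif planted counts).
#' @export
make_smn_fragments <- function(genotype = c("control", "sma"),
                               n_fragments,
                               inclusion_rate,
                               read_length = 100L,
                               seed = 1L,
                               strand = c("sense", "antisense"),
                               both_junction_same_mate = FALSE) {
  genotype <- match.arg(genotype)
  strand <- match.arg(strand)
  stopifnot(n_fragments >= 0, inclusion_rate >= 0, inclusion_rate <= 1)
  catalog <- compile_catalog()
  max_motif <- max(nchar(ifelse(is.na(catalog$part2), catalog$part1,
                                paste0(catalog$part1, catalog$part2))))
  if (read_length < max(20L, max_motif)) {
    stop("read_length must be >= 20 and at least the longest catalog motif (",
         max_motif, " nt)")
  }
  n_fragments <- as.integer(n_fragments)
  read_length <- as.integer(read_length)

  reads <- with_seed(seed, {
    m1 <- random_dna(n_fragments, read_length)
    m2 <- random_dna(n_fragments, read_length)
    if (n_fragments > 0L) {
      has_exon7 <- stats::runif(n_fragments) < inclusion_rate
      pattern_kind <- ifelse(
        has_exon7,
        sample(c("exon7_start", "e6e7", "e7e8", "both"), n_fragments,
               replace = TRUE),
        "background"
      )
      gene <- if (genotype == "sma") {
        rep("SMN2", n_fragments)
      } else {
        sample(c("SMN1", "SMN2"), n_fragments, replace = TRUE)
      }
      for (i in seq_len(n_fragments)) {
        kind <- pattern_kind[i]
        if (kind == "background") next
        if (kind == "both") {
          nm <- paste0("both_junctions_", gene[i])
          row <- catalog[catalog$name == nm, ]
          p1 <- orient(row$part1, strand)
          p2 <- orient(row$part2, strand)
          if (both_junction_same_mate) {
            mate <- sample(1:2, 1L)
            seqs <- plant_two(if (mate == 1L) m1[i] else m2[i], p1, p2)
            if (mate == 1L) m1[i] <- seqs else m2[i] <- seqs
          } else {
            m1[i] <- plant_one(m1[i], p1)
            m2[i] <- plant_one(m2[i], p2)
          }
        } else {
          nm <- switch(kind,
            exon7_start = paste0("exon7_start_", gene[i]),
            e6e7 = paste0("e6e7_junction_", gene[i]),
            e7e8 = "e7e8_junction"
          )
          row <- catalog[catalog$name == nm, ]
          pat <- orient(paste0(row$part1,
                               ifelse(is.na(row$part2), "", row$part2)),
                        strand)
          mate <- sample(1:2, 1L)
          if (mate == 1L) m1[i] <- plant_one(m1[i], pat)
          else m2[i] <- plant_one(m2[i], pat)
        }
      }
    }
    read_pair_set(
      ids = sprintf("frag%06d", seq_len(n_fragments)),
      mate1 = m1, mate2 = m2, read_length = read_length, seed = seed
    )
  })

  planted <- naive_motif_tally(reads$mate1, reads$mate2, catalog,
                               strand = strand)
  truth <- structure(
    list(genotype = genotype, inclusion_rate = inclusion_rate,
         planted_counts = planted, strand = strand),
    class = "smn_truth"
  )
  list(reads = reads, truth = truth)
}

orient <- function(pattern, strand) {
  if (strand == "antisense") reverse_complement(pattern) else pattern
}

# Overwrite a random window of a read with the pattern.
plant_one <- function(seq, pattern) {
  L <- nchar(seq); k <- nchar(pattern)
  off <- sample.int(L - k + 1L, 1L)
  paste0(substr(seq, 1L, off - 1L), pattern, substr(seq, off + k, L))
}

# Plant two patterns into one read without overlap: first in the left half,
# second in the right half.
plant_two <- function(seq, p1, p2) {
  L <- nchar(seq); k1 <- nchar(p1); k2 <- nchar(p2)
  half <- L %/% 2L
  off1 <- sample.int(half - k1 + 1L, 1L)
  off2 <- half + sample.int(L - half - k2 + 1L, 1L)
  out <- paste0(substr(seq, 1L, off1 - 1L), p1,
                substr(seq, off1 + k1, L))
  paste0(substr(out, 1L, off2 - 1L), p2, substr(out, off2 + k2, L))
}

#' Construct a paired-end fragment set
#'
#' @param ids unique fragment ids.
#' @param mate1,mate2 character vectors of equal-length A/C/G/T sequences.
#' @param read_length mate length in nt.
#' @param seed seed recorded for provenance (may be `NA` for file-derived
#'   sets).
#' @return object of class `read_pair_set`.
#' @export
read_pair_set <- function(ids, mate1, mate2, read_length, seed = NA_integer_) {
  stopifnot(length(ids) == length(mate1), length(mate1) == length(mate2),
            !anyDuplicated(ids))
  if (length(mate1) > 0L &&
      (any(nchar(mate1) != read_length) || any(nchar(mate2) != read_length))) {
    stop("all mates must have length read_length")
  }
  structure(list(ids = ids, mate1 = mate1, mate2 = mate2,
                 read_length = as.integer(read_length), seed = seed),
            class = "read_pair_set")
}

#' @export
length.read_pair_set <- function(x) length(x$ids)

#' @export
print.read_pair_set <- function(x, ...) {
  cat("read_pair_set:", length(x$ids), "fragments, 2 x", x$read_length,
      "bp\n")
  invisible(x)
}

# Naive fragment-level motif tally by base-R fixed substring search; used to
# compute ground-truth planted counts post hoc from the emitted reads.
# A fragment counts at most once per motif; paired ("&") motifs require both
# subsequences within the fragment (either mate).
naive_motif_tally <- function(mate1, mate2, catalog, strand = "sense") {
  out <- integer(nrow(catalog))
  names(out) <- catalog$name
  for (i in seq_len(nrow(catalog))) {
    if (isTRUE(catalog$paired[i])) {
      p1 <- orient(catalog$part1[i], strand)
      p2 <- orient(catalog$part2[i], strand)
      hit <- (grepl(p1, mate1, fixed = TRUE) | grepl(p1, mate2, fixed = TRUE)) &
             (grepl(p2, mate1, fixed = TRUE) | grepl(p2, mate2, fixed = TRUE))
    } else {
      pat <- orient(paste0(catalog$part1[i],
                           ifelse(is.na(catalog$part2[i]), "",
                                  catalog$part2[i])), strand)
      hit <- grepl(pat, mate1, fixed = TRUE) | grepl(pat, mate2, fixed = TRUE)
    }
    out[i] <- sum(hit)
  }
  out
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts are drawn feature-wise from a negative binomial with dispersion
#' `dispersion` (variance = mu + dispersion * mu^2). Group A features have
#' mean `baseline_mean`; group B means are `baseline_mean * 2^log2fc` for the
#' planted features and `baseline_mean` otherwise.
#'
#' @param n_features number of features.
#' @param group_sizes integer pair `(nA, nB)`, each >= 1; the study design
#'   default is 10 vs 10.
#' @param planted_effects named numeric vector of true log2 fold changes
#'   (B vs A); names must be among the generated feature ids.
#' @param baseline_mean positive mean count in group A.
#' @param dispersion NB dispersion (> 0).
#' @param feature_class `"lnRNA"` or `"sRNA"` (controls id prefixes and the
#'   downstream filter thresholds).
#' @param seed integer RNG seed.
#' @return list with `matrix` (a `count_matrix`) and `truth` (a `de_truth`
#'   with planted log2 fold changes; unnamed features have true log2FC 0).
#' @export
make_count_matrix <- function(n_features,
                              group_sizes = c(10L, 10L),
                              planted_effects = numeric(0),
                              baseline_mean = 200,
                              dispersion = 0.1,
                              feature_class = c("lnRNA", "sRNA"),
                              seed = 1L) {
  feature_class <- match.arg(feature_class)
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 1L),
            dispersion > 0)
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  prefix <- if (feature_class == "lnRNA") "gene" else "mir"
  features <- sprintf("%s%04d", prefix, seq_len(n_features))
  if (length(planted_effects) &&
      !all(names(planted_effects) %in% features)) {
    stop("planted_effects keys must be generated feature ids")
  }
  nA <- as.integer(group_sizes[1]); nB <- as.integer(group_sizes[2])
  samples <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
  groups <- stats::setNames(rep(c("A", "B"), c(nA, nB)), samples)

  lfc <- stats::setNames(numeric(n_features), features)
  lfc[names(planted_effects)] <- planted_effects
  mu <- cbind(matrix(baseline_mean, n_features, nA),
              matrix(baseline_mean * 2^lfc, n_features, nB))
  counts <- with_seed(seed, {
    matrix(stats::rnbinom(n_features * (nA + nB), mu = mu,
                          size = 1 / dispersion),
           n_features, nA + nB, dimnames = list(features, samples))
  })
  storage.mode(counts) <- "integer"
  list(
    matrix = count_matrix(counts, feature_class, groups),
    truth = structure(
      list(planted_log2fc = planted_effects, baseline_mean = baseline_mean,
           dispersion = dispersion),
      class = "de_truth"
    )
  )
}

#' Construct a count matrix with group labels
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param feature_class `"lnRNA"` or `"sRNA"`.
#' @param groups named character vector mapping every sample to `"A"` or
#'   `"B"`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, feature_class = c("lnRNA", "sRNA"), groups) {
  feature_class <- match.arg(feature_class)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (!all(colnames(counts) %in% names(groups))) {
    stop("every sample must have a group label")
  }
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("A", "B"))) stop("group labels must be 'A' or 'B'")
  structure(list(counts = counts, feature_class = feature_class,
                 groups = groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix (", x$feature_class, "): ", nrow(x$counts),
      " features x ", ncol(x$counts), " samples (",
      sum(x$groups == "A"), " A vs ", sum(x$groups == "B"), " B)\n",
      sep = "")
  invisible(x)
}

#' Simulate a miRNA-target interaction database
#'
#' Emulates the union of an experimentally validated interaction resource
#' and several target-prediction algorithms. Each true (miRNA, gene) pair is
#' recorded as `validated` with probability `validated_fraction` and,
#' independently per predictor, as `predicted:<algorithm>` with probability
#' `per_predictor_recall`. Spurious predicted links over non-true pairs are
#' added per predictor at `false_link_rate`.
#'
#' @param mirna_ids,gene_ids id universes.
#' @param true_pairs data frame with columns `mirna`, `gene` (must reference
#'   known ids).
#' @param validated_fraction,per_predictor_recall,false_link_rate rates in
#'   `[0, 1]`.
#' @param predictors non-empty character vector of predictor names; the
#'   default is the five algorithms of the study design.
#' @param seed integer RNG seed.
#' @return list with `db` (an `interaction_db`: data frame `mirna`, `gene`,
#'   `source`) and `truth` (the `true_pairs` data frame).
#' @export
make_interaction_db <- function(mirna_ids, gene_ids, true_pairs,
                                validated_fraction = 0.5,
                                predictors = c("miRanda", "RNAhybrid",
                                               "RNA22", "miRDB",
                                               "TargetScan"),
                                per_predictor_recall = 0.5,
                                false_link_rate = 0.01,
                                seed = 1L) {
  rates <- c(validated_fraction, per_predictor_recall, false_link_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), length(predictors) >= 1L)
  if (!all(true_pairs$mirna %in% mirna_ids) ||
      !all(true_pairs$gene %in% gene_ids)) {
    stop("true_pairs reference unknown miRNA or gene ids")
  }
  all_pairs <- expand.grid(mirna = mirna_ids, gene = gene_ids,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$mirna, d$gene, sep = "\r")
  is_true <- key(all_pairs) %in% key(true_pairs)

  records <- with_seed(seed, {
    recs <- list()
    n_true <- nrow(true_pairs)
    if (n_true > 0L) {
      val <- stats::runif(n_true) < validated_fraction
      if (any(val)) {
        recs[[length(recs) + 1L]] <- data.frame(
          mirna = true_pairs$mirna[val], gene = true_pairs$gene[val],
          source = "validated", stringsAsFactors = FALSE)
      }
    }
    for (alg in predictors) {
      if (n_true > 0L) {
        hit <- stats::runif(n_true) < per_predictor_recall
        if (any(hit)) {
          recs[[length(recs) + 1L]] <- data.frame(
            mirna = true_pairs$mirna[hit], gene = true_pairs$gene[hit],
            source = paste0("predicted:", alg), stringsAsFactors = FALSE)
        }
      }
      false_pool <- all_pairs[!is_true, , drop = FALSE]
      if (nrow(false_pool) > 0L && false_link_rate > 0) {
        fp <- stats::runif(nrow(false_pool)) < false_link_rate
        if (any(fp)) {
          recs[[length(recs) + 1L]] <- data.frame(
            mirna = false_pool$mirna[fp], gene = false_pool$gene[fp],
            source = paste0("predicted:", alg), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(recs)) do.call(rbind, recs) else
      data.frame(mirna = character(0), gene = character(0),
                 source = character(0), stringsAsFactors = FALSE)
  })
  records <- unique(records)
  rownames(records) <- NULL
  class(records) <- c("interaction_db", "data.frame")
  list(db = records, truth = true_pairs)
}

#' Simulate a test network: Erdos-Renyi background plus one planted clique
#'
#' @param n_nodes number of nodes.
#' @param planted_clique_size clique size (<= `n_nodes`); the clique is
#'   planted on the first nodes and marked by the vertex attribute
#'   `in_clique`.
#' @param background_edge_prob edge probability of the background graph, in
#'   `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an undirected simple `igraph` graph with named vertices.
#' @export
make_test_network <- function(n_nodes, planted_clique_size = 0L,
                              background_edge_prob = 0.05, seed = 1L) {
  stopifnot(planted_clique_size <= n_nodes)
  if (background_edge_prob < 0 || background_edge_prob > 1) {
    stop("background_edge_prob must be in [0, 1]")
  }
  g <- with_seed(seed, {
    igraph::sample_gnp(n_nodes, background_edge_prob, directed = FALSE)
  })
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n_nodes))
  if (planted_clique_size >= 2L) {
    clique_edges <- t(utils::combn(seq_len(planted_clique_size), 2L))
    g <- igraph::add_edges(g, t(clique_edges))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$in_clique <- seq_len(n_nodes) <= planted_clique_size
  g
}
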