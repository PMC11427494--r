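# SMN1/SMN2 discriminant-motif and junction-spanning read quantification.
#
# SMN1 and SMN2 are near-identical paralogs that differ at a single C/T base
# in exon 7; reads covering exon boundaries can therefore be assigned to a
# gene only when the match overlaps that discriminant base. The catalog holds
# the seven exon-7 subsequences searched in the reads: the exon-7 start from
# each gene, the exon6-exon7 junction from each gene (a junction-spanning
# read must contain the concatenation of the two exon-side parts), the
# gene-unspecific exon7-exon8 junction, and the paired both-junction
# patterns whose two subsequences are looked for within one paired-end
# fragment.

#' Compile the SMN exon-7 motif catalog
#'
#' Returns the seven discriminant subsequences used to detect exon-7
#' inclusion in SMN1/SMN2 reads. Junction entries are stored as the two
#' exon-side parts; for single-fragment search the parts of an
#' exon6-exon7 or exon7-exon8 entry are concatenated (a read must span the
#' junction), while `both_junctions_*` entries keep their two subsequences
#' separate and require both within one fragment.
#'
#' @param include_reverse_complement if `TRUE` (default), downstream search
#'   also matches the reverse complement of each pattern, since library
#'   strandedness is not asserted.
#' @return a `motif_catalog`: data frame with columns `name`, `part1`,
#'   `part2` (`NA` for single-string entries), `paired` (TRUE for
#'   both-junction entries), `gene` (`"SMN1"`, `"SMN2"` or `NA`),
#'   `discriminant` (does the pattern cover the C/T discriminant base?),
#'   and attribute `revcomp`.
#' @export
compile_catalog <- function(include_reverse_complement = TRUE) {
  cat <- data.frame(
    name = c("exon7_start_SMN1", "exon7_start_SMN2",
             "e6e7_junction_SMN1", "e6e7_junction_SMN2",
             "e7e8_junction",
             "both_junctions_SMN1", "both_junctions_SMN2"),
    part1 = c("GGTTTCAGACAAAAT", "GGTTTTAGACAAAAT",
              "TATTATATG", "TATTATATG",
              "AATTAAGGA",
              "TATATGGGTTTC", "TATATGGGTTTT"),
    part2 = c(NA, NA,
              "GGTTTCAGA", "GGTTTTAGA",
              "GAAATGCTG",
              "TAAGGAGAAATG", "TAAGGAGAAATG"),
    paired = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    gene = c("SMN1", "SMN2", "SMN1", "SMN2", NA, "SMN1", "SMN2"),
    discriminant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  attr(cat, "revcomp") <- isTRUE(include_reverse_complement)
  class(cat) <- c("motif_catalog", "data.frame")
  cat
}

# Search strings of a catalog row for single-fragment matching: one string
# for single and junction-concatenation entries, two for paired entries.
catalog_search_strings <- function(row) {
  if (isTRUE(row$paired)) c(row$part1, row$part2)
  else paste0(row$part1, ifelse(is.na(row$part2), "", row$part2))
}

# Fragment-level match indicator for one pattern across both mates,
# optionally also matching the reverse complement. Biostrings fixed matching
# means ambiguity codes in reads never match.
fragment_has_pattern <- function(m1, m2, pattern, revcomp) {
  hit <- Biostrings::vcountPattern(pattern, m1, fixed = TRUE) > 0L |
         Biostrings::vcountPattern(pattern, m2, fixed = TRUE) > 0L
  if (revcomp) {
    rc <- reverse_complement(pattern)
    hit <- hit |
      Biostrings::vcountPattern(rc, m1, fixed = TRUE) > 0L |
      Biostrings::vcountPattern(rc, m2, fixed = TRUE) > 0L
  }
  hit
}

mate_has_pattern <- function(mate, pattern, revcomp) {
  hit <- Biostrings::vcountPattern(pattern, mate, fixed = TRUE) > 0L
  if (revcomp) {
    hit <- hit | Biostrings::vcountPattern(reverse_complement(pattern),
                                           mate, fixed = TRUE) > 0L
  }
  hit
}

#' Count SMN motif-bearing fragments
#'
#' Tallies, per catalog motif, the number of fragments matching it: a
#' single-pattern motif matches when its search string occurs in either
#' mate; a paired (both-junction) motif matches when both subsequences occur
#' within the fragment — by default in either mate or the same mate, or
#' strictly in opposite mates with `paired_strict = TRUE`. A fragment counts
#' at most once per motif (the unit is reads, not occurrences). The
#' ambiguous fraction is the share of SMN-matching fragments whose matches
#' never cover the C/T discriminant base (i.e. fragments matching only the
#' gene-unspecific exon7-exon8 junction), reflecting how little of the
#' paralog pair is distinguishable at the read level.
#'
#' @param reads a `read_pair_set`.
#' @param catalog a `motif_catalog` from [compile_catalog()].
#' @param paired_strict require the two subsequences of a both-junction
#'   motif to fall in opposite mates.
#' @param sample_id label carried into the result.
#' @return an `smn_counts`: per-motif tallies, total fragments, number of
#'   SMN-matching fragments and `ambiguous_fraction` (`NA` when no fragment
#'   matches any motif).
#' @export
count_motifs <- function(reads, catalog = compile_catalog(),
                         paired_strict = FALSE, sample_id = "sample") {
  if (nrow(catalog) == 0L) stop("empty motif catalog")
  revcomp <- isTRUE(attr(catalog, "revcomp"))
  n <- length(reads$ids)
  if (n == 0L) {
    tallies <- stats::setNames(integer(nrow(catalog)), catalog$name)
    return(smn_counts(sample_id, tallies, 0L, 0L, 0L))
  }
  m1 <- Biostrings::DNAStringSet(reads$mate1)
  m2 <- Biostrings::DNAStringSet(reads$mate2)

  hits <- matrix(FALSE, n, nrow(catalog),
                 dimnames = list(NULL, catalog$name))
  for (i in seq_len(nrow(catalog))) {
    row <- catalog[i, ]
    if (isTRUE(row$paired)) {
      h1m1 <- mate_has_pattern(m1, row$part1, revcomp)
      h1m2 <- mate_has_pattern(m2, row$part1, revcomp)
      h2m1 <- mate_has_pattern(m1, row$part2, revcomp)
      h2m2 <- mate_has_pattern(m2, row$part2, revcomp)
      hits[, i] <- if (paired_strict) {
        (h1m1 & h2m2) | (h1m2 & h2m1)
      } else {
        (h1m1 | h1m2) & (h2m1 | h2m2)
      }
    } else {
      pat <- catalog_search_strings(row)
      hits[, i] <- fragment_has_pattern(m1, m2, pat, revcomp)
    }
  }
  any_hit <- rowSums(hits) > 0L
  disc_hit <- rowSums(hits[, catalog$discriminant, drop = FALSE]) > 0L
  smn_counts(
    sample_id,
    tallies = stats::setNames(as.integer(colSums(hits)), catalog$name),
    total_fragments = n,
    n_smn_fragments = sum(any_hit),
    n_ambiguous = sum(any_hit & !disc_hit)
  )
}

smn_counts <- function(sample_id, tallies, total_fragments, n_smn_fragments,
                       n_ambiguous) {
  stopifnot(all(tallies >= 0L))
  structure(
    list(sample_id = sample_id, tallies = tallies,
         total_fragments = as.integer(total_fragments),
         n_smn_fragments = as.integer(n_smn_fragments),
         n_ambiguous = as.integer(n_ambiguous),
         ambiguous_fraction = if (n_smn_fragments > 0L)
           n_ambiguous / n_smn_fragments else NA_real_),
    class = "smn_counts"
  )
}

#' @export
print.smn_counts <- function(x, ...) {
  cat("smn_counts [", x$sample_id, "]: ", x$total_fragments,
      " fragments, ", x$n_smn_fragments, " SMN-matching\n", sep = "")
  print(x$tallies)
  invisible(x)
}

#' Fraction of SMN-matching fragments that cannot be assigned to a gene
#'
#' @param counts an `smn_counts` from [count_motifs()].
#' @return the ambiguous fraction in `[0, 1]`; `NA_real_` (undefined,
#'   distinct from 0) when no fragment matched any SMN motif.
#' @export
ambiguity_report <- function(counts) {
  stopifnot(inherits(counts, "smn_counts"))
  if (counts$n_smn_fragments == 0L) {
    warning("no SMN-matching fragments; ambiguous fraction undefined")
    return(NA_real_)
  }
  counts$ambiguous_fraction
}

#' Exon-7 fold change between baseline and follow-up
#'
#' Normalizes each motif tally by its sample scaling factor (the stand-in
#' for model-based library-size factors; see [scaling_factors()]) and flags
#' motifs whose normalized follow-up / baseline ratio strictly exceeds 1.5.
#' A zero baseline with positive follow-up gives `Inf` (flagged); two zeros
#' give `NA` (undefined, not flagged).
#'
#' @param counts_t0,counts_t10 `smn_counts` for the two time points, over
#'   the same catalog.
#' @param factors positive numeric pair: scaling factors for (t0, t10).
#' @param fc_threshold flagging threshold (default 1.5, strict `>`).
#' @return data frame: `motif`, `normalized_t0`, `normalized_t10`,
#'   `fold_change`, `increased`.
#' @export
exon7_fold_change <- function(counts_t0, counts_t10, factors = c(1, 1),
                              fc_threshold = 1.5) {
  stopifnot(length(factors) == 2L, all(factors > 0))
  if (!identical(names(counts_t0$tallies), names(counts_t10$tallies))) {
    stop("the two counts must come from the same catalog")
  }
  if (any(counts_t0$tallies < 0L) || any(counts_t10$tallies < 0L)) {
    stop("negative tallies")
  }
  n0 <- counts_t0$tallies / factors[1]
  n10 <- counts_t10$tallies / factors[2]
  fc <- ifelse(n0 > 0, n10 / n0, ifelse(n10 > 0, Inf, NA_real_))
  data.frame(
    motif = names(counts_t0$tallies),
    normalized_t0 = unname(n0),
    normalized_t10 = unname(n10),
    fold_change = unname(fc),
    increased = unname(!is.na(fc) & fc > fc_threshold),
    stringsAsFactors = FALSE
  )
}

#' Paired one-tailed trend test for SMN2 expression under treatment
#'
#' Tests for an increase from baseline (T0) to follow-up (T10) in paired
#' per-patient normalized SMN2 expression values, using the exact one-sided
#' Wilcoxon signed-rank test (full enumeration of sign assignments).
#'
#' @param values_t0,values_t10 paired numeric vectors of equal length.
#' @return a `wilcoxon_result`; see [exact_wilcoxon_one_tailed()].
#' @export
smn2_trend_test <- function(values_t0, values_t10) {
  exact_wilcoxon_one_tailed(values_t0, values_t10, alternative = "greater")
}
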