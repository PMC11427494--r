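# SMN1/SMN2 motif catalog, junction counting, ambiguity, exon-7 fold
# change, and the paired trend test.

# fragment fixtures on a motif-free poly-A background
frag_fixture <- function(mate1_inserts = list(), mate2_inserts = list(),
                         n = max(length(mate1_inserts),
                                 length(mate2_inserts)),
                         read_length = 100L) {
  bg <- strrep("A", read_length)
  embed <- function(ins) {
    if (is.null(ins) || !nzchar(ins)) return(bg)
    paste0(substr(bg, 1, 10), ins,
           substr(bg, 1, read_length - 10 - nchar(ins)))
  }
  m1 <- vapply(seq_len(n), function(i) {
    embed(if (i <= length(mate1_inserts)) mate1_inserts[[i]] else "")
  }, character(1))
  m2 <- vapply(seq_len(n), function(i) {
    embed(if (i <= length(mate2_inserts)) mate2_inserts[[i]] else "")
  }, character(1))
  read_pair_set(sprintf("f%03d", seq_len(n)), m1, m2, read_length)
}

test_that("the catalog holds the seven discriminant entries", {
  cat7 <- compile_catalog()
  expect_identical(nrow(cat7), 7L)
  expect_identical(cat7$part1[cat7$name == "exon7_start_SMN1"],
                   "GGTTTCAGACAAAAT")
  expect_identical(cat7$part1[cat7$name == "exon7_start_SMN2"],
                   "GGTTTTAGACAAAAT")
  # SMN1 and SMN2 exon-7 starts differ at exactly one position (0-based 5)
  s1 <- strsplit(cat7$part1[cat7$name == "exon7_start_SMN1"], "")[[1]]
  s2 <- strsplit(cat7$part1[cat7$name == "exon7_start_SMN2"], "")[[1]]
  expect_identical(which(s1 != s2), 6L)
  expect_identical(s1[6], "C")
  expect_identical(s2[6], "T")
  # junction entries concatenate their exon-side parts for search
  e6e7 <- cat7[cat7$name == "e6e7_junction_SMN2", ]
  expect_identical(paste0(e6e7$part1, e6e7$part2), "TATTATATGGGTTTTAGA")
  expect_identical(reverse_complement("GGTTTTAGACAAAAT"), "ATTTTGTCTAAAACC")
})

test_that("single-pattern motifs count fragments, not occurrences, in either mate", {
  reads <- frag_fixture(mate1_inserts = list("GGTTTTAGACAAAAT"))
  ct <- count_motifs(reads, sample_id = "fx")
  expect_identical(unname(ct$tallies["exon7_start_SMN2"]), 1L)
  expect_identical(unname(ct$tallies["exon7_start_SMN1"]), 0L)

  # two occurrences in one fragment still count once
  reads2 <- frag_fixture(mate1_inserts = list(
    strrep("GGTTTTAGACAAAAT", 2)))
  expect_identical(
    unname(count_motifs(reads2)$tallies["exon7_start_SMN2"]), 1L)

  # motif in mate2 counts the same
  reads3 <- frag_fixture(mate2_inserts = list("GGTTTTAGACAAAAT"))
  expect_identical(
    unname(count_motifs(reads3)$tallies["exon7_start_SMN2"]), 1L)

  empty <- read_pair_set(character(0), character(0), character(0), 100L)
  expect_true(all(count_motifs(empty)$tallies == 0L))
  expect_error(count_motifs(reads, compile_catalog()[0, ]), "empty")
})

test_that("both-junction motifs require both subsequences within the fragment", {
  # opposite mates (the paired-end convention)
  reads <- frag_fixture(mate1_inserts = list("TATATGGGTTTT"),
                        mate2_inserts = list("TAAGGAGAAATG"))
  expect_identical(
    unname(count_motifs(reads)$tallies["both_junctions_SMN2"]), 1L)
  expect_identical(
    unname(count_motifs(reads,
                        paired_strict = TRUE)$tallies["both_junctions_SMN2"]),
    1L)

  # same mate: counted by default, rejected under the strict opposite-mate
  # mode
  reads2 <- frag_fixture(mate1_inserts = list(
    paste0("TATATGGGTTTT", "AAAA", "TAAGGAGAAATG")))
  expect_identical(
    unname(count_motifs(reads2)$tallies["both_junctions_SMN2"]), 1L)
  expect_identical(
    unname(count_motifs(reads2,
                        paired_strict = TRUE)$tallies["both_junctions_SMN2"]),
    0L)

  # one subsequence alone never counts
  reads3 <- frag_fixture(mate1_inserts = list("TATATGGGTTTT"))
  expect_identical(
    unname(count_motifs(reads3)$tallies["both_junctions_SMN2"]), 0L)
})

test_that("reverse-complement search is applied only when enabled", {
  rc <- reverse_complement("GGTTTTAGACAAAAT")
  reads <- frag_fixture(mate1_inserts = list(rc))
  on_ct <- count_motifs(reads, compile_catalog(TRUE))
  off_ct <- count_motifs(reads, compile_catalog(FALSE))
  expect_identical(unname(on_ct$tallies["exon7_start_SMN2"]), 1L)
  expect_identical(unname(off_ct$tallies["exon7_start_SMN2"]), 0L)
})

test_that("ambiguous fraction reflects fragments never covering the discriminant base", {
  e7e8 <- paste0("AATTAAGGA", "GAAATGCTG")
  only_shared <- frag_fixture(mate1_inserts = rep(list(e7e8), 4))
  expect_equal(ambiguity_report(count_motifs(only_shared)), 1.0)

  only_disc <- frag_fixture(mate1_inserts = rep(list("GGTTTTAGACAAAAT"), 4))
  expect_equal(ambiguity_report(count_motifs(only_disc)), 0.0)

  half <- frag_fixture(mate1_inserts = c(rep(list(e7e8), 2),
                                         rep(list("GGTTTTAGACAAAAT"), 2)))
  expect_equal(ambiguity_report(count_motifs(half)), 0.5)

  none <- frag_fixture(n = 3)
  expect_warning(val <- ambiguity_report(count_motifs(none)), "undefined")
  expect_identical(val, NA_real_)
})

test_that("count_motifs equals the naive positional-scan oracle on synthetic fixtures", {
  for (case in list(list(gt = "control", rate = 0.5, strict = FALSE),
                    list(gt = "sma", rate = 0.8, strict = FALSE),
                    list(gt = "control", rate = 0.3, strict = TRUE))) {
    sim <- make_smn_fragments(case$gt, 400L, case$rate, seed = 31L)
    catalog <- compile_catalog()
    got <- count_motifs(sim$reads, catalog, paired_strict = case$strict)
    want <- oracle_motif_tally(sim$reads, catalog,
                               paired_strict = case$strict)
    expect_identical(got$tallies, want,
                     info = paste(case, collapse = "/"))
  }
})

test_that("adding a motif-bearing fragment is monotone and local", {
  base <- make_smn_fragments("control", 50L, 0.5, seed = 8L)$reads
  before <- count_motifs(base)$tallies
  extra <- frag_fixture(mate1_inserts = list("GGTTTTAGACAAAAT"))
  grown <- read_pair_set(c(base$ids, "extra1"),
                         c(base$mate1, extra$mate1),
                         c(base$mate2, extra$mate2), base$read_length)
  after <- count_motifs(grown)$tallies
  expect_identical(unname(after["exon7_start_SMN2"] -
                            before["exon7_start_SMN2"]), 1L)
  others <- setdiff(names(before), "exon7_start_SMN2")
  expect_identical(after[others], before[others])
})

test_that("estimated exon-7 inclusion is monotone in the generator rate", {
  est <- vapply(c(0.2, 0.5, 0.8), function(p) {
    sim <- make_smn_fragments("control", 5000L, p,
                              seed = 600L + round(10 * p))
    ct <- count_motifs(sim$reads)
    ct$n_smn_fragments / ct$total_fragments
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("exon-7 fold change flags strictly above 1.5 and handles zeros", {
  mk <- function(tallies) {
    smaseq:::smn_counts("s", tallies, sum(tallies), sum(tallies), 0L)
  }
  nm <- compile_catalog()$name
  t0 <- stats::setNames(c(10L, 10L, 0L, 0L, 5L, 3L, 3L), nm)
  t10 <- stats::setNames(c(20L, 14L, 4L, 0L, 5L, 3L, 6L), nm)
  rep <- exon7_fold_change(mk(t0), mk(t10), factors = c(1, 1))
  expect_equal(rep$fold_change[1], 2.0)
  expect_true(rep$increased[1])
  expect_equal(rep$fold_change[2], 1.4)
  expect_false(rep$increased[2])              # strict inequality at 1.5
  expect_identical(rep$fold_change[3], Inf)   # 0 -> positive
  expect_true(rep$increased[3])
  expect_identical(rep$fold_change[4], NA_real_)  # 0 -> 0: undefined
  expect_false(rep$increased[4])
  expect_equal(rep$fold_change[5], 1.0)
  expect_false(rep$increased[5])

  # normalization by the scaling factors
  rep2 <- exon7_fold_change(mk(t0), mk(t10), factors = c(2, 1))
  expect_equal(rep2$normalized_t0[1], 5)
  expect_equal(rep2$fold_change[1], 4)

  expect_error(exon7_fold_change(mk(t0), mk(t10), factors = c(0, 1)),
               "factors")
})

test_that("the SMN2 trend test is the exact one-sided signed-rank test for increase", {
  r <- smn2_trend_test(c(1, 2, 3, 4, 5, 6), c(7, 8, 9, 10, 11, 12))
  expect_equal(r$p_one_sided, 1 / 64)
  expect_identical(r$alternative, "greater")
  expect_error(smn2_trend_test(1:5, 1:5), class = "smaseq_degenerate_error")
  expect_error(smn2_trend_test(1:3, 1:4), "equal length")
})
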