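# smaseq

Transcriptomic analysis pipeline for adult spinal muscular atrophy (SMA)
under nusinersen, exercised end to end on synthetic data with known ground
truth.

## What it is for

SMA is caused by loss of *SMN1*; the near-identical paralog *SMN2* carries
a single C→T change in exon 7 that makes most of its transcripts skip
exon 7. Nusinersen promotes exon-7 inclusion. For anyone analysing bulk
RNA-seq of treated patients, this package implements the complete
computational chain such a study needs:

* **SMN1/SMN2 exon-7 quantification** — counting paired-end fragments that
  carry the discriminant exon-7 start motifs (`GGTTTCAGACAAAAT` for SMN1 /
  `GGTTTTAGACAAAAT` for SMN2), the junction-spanning concatenations
  exon6–exon7 (`TATTATATG`+`GGTTT{C,T}AGA`) and exon7–exon8
  (`AATTAAGGA`+`GAAATGCTG`), and the paired both-junction patterns, with
  an ambiguity report for fragments that never cover the discriminant
  base. Flags exon-7 increases by the strict rule FC > 1.5 on normalized
  tallies.
* **Exact paired trend test** — one-sided Wilcoxon signed-rank by full
  enumeration of the 2^n sign assignments:
  p = P(W⁺ ≥ w | H₀), exact even with mid-ranked ties.
* **Differential expression** — median-of-ratios normalization, a
  seed-reproducible permutation test on group means of log2(q + 0.5), BH
  FDR, and the study filter cascade (FDR ≤ 0.05; mean count > 50 for long
  RNA / > 20 for small RNA; |log2FC| > 1 / > 0.585), plus the
  "restored-at-follow-up" set logic.
* **miRNA–target integration** — inverse-expression candidate pairs
  (miRNA up × gene down and vice versa) annotated against an interaction
  database, validated support dominating predicted.
* **Hub-gene scoring** — degree, maximal clique centrality
  MCC(v) = Σ_{C∋v} (|C|−1)!, DMNC = |E(MNC)|/|V(MNC)|^1.7, reciprocal
  closeness, radiality, bottleneck (BFS shortest-path-tree descendants
  > n_c/4), betweenness, and clustering coefficient, each verified against
  brute force.
* **Enrichment** — Fisher-exact (hypergeometric upper tail) over GMT gene
  sets with BH and Bonferroni corrections.
* **Synthetic data generators** for all of the above: junction-bearing
  2×100 bp read pairs at a controllable exon-7 inclusion rate,
  negative-binomial count matrices with planted log2 fold changes,
  interaction databases with tunable recall/noise, and planted-clique test
  networks.

## Worked example

```r
library(smaseq)

# SMA genotype: SMN1 is deleted, so no SMN1-discriminant read can exist
sim <- make_smn_fragments("sma", n_fragments = 1000, inclusion_rate = 0.5,
                          seed = 42)
counts <- count_motifs(sim$reads, compile_catalog())
counts
#> smn_counts [sample]: 1000 fragments, 527 SMN-matching
#>    exon7_start_SMN1    exon7_start_SMN2  e6e7_junction_SMN1  e6e7_junction_SMN2
#>                   0                 127                   0                 132
#>       e7e8_junction both_junctions_SMN1 both_junctions_SMN2
#>                 125                   0                 143
```

All SMN1 tallies are zero (the genotype makes them structurally
impossible), the SMN2 exon-7 motifs split roughly evenly across the four
planted pattern kinds, and 125/527 fragments carry only the
gene-unspecific exon7–exon8 junction — the ambiguous fraction.

```r
# paired SMN2 expression, six patients, five increases, the lone decrease
# having the second-smallest absolute difference
t0  <- c(10, 20, 30, 40, 50, 60)
t10 <- t0 + c(6, 5, 4, -3, 2, 8)
smn2_trend_test(t0, t10)
#> exact one-sided Wilcoxon signed-rank test (greater)
#> n (nonzero) = 6, W+ = 19, W- = 2
#> p = 0.046875 (quoted to 3 decimals: 0.046)
```

The exact p-value is 3/64: of the 64 equiprobable sign assignments, only
three give a positive-rank sum of at least 19.

The full analysis workflow is in `analysis/01_simulate_data.R` …
`analysis/06_enrichment.R` — numbered drivers that simulate the cohort,
quantify SMN exon-7 inclusion, run both DE contrasts with the filter
cascade, integrate miRNA targets, score network hubs, and test
enrichment, writing their tables under `results/`. A single-call
equivalent is `run_pipeline(pipeline_config(seed = 7), "results/run")`.

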