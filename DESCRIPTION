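Package: smaseq
Title: Transcriptomic Pipeline for Adult SMA Under Nusinersen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, on fully synthetic data with known ground truth,
    a bulk-transcriptomic analysis of adult spinal muscular atrophy (SMA)
    patients treated with nusinersen: discriminant-motif counting of
    SMN1/SMN2 exon-7 junction-spanning reads, read-ambiguity reporting,
    median-of-ratios normalization with an exon-7 fold-change rule, an exact
    paired one-tailed Wilcoxon signed-rank trend test, a permutation-based
    differential-expression engine with the study's filter cascade and
    restored-at-follow-up set logic, inverse-expression miRNA-target
    integration with validated/predicted labeling, hub-gene centrality
    scoring (degree, MCC, DMNC, closeness, radiality, bottleneck,
    betweenness, clustering coefficient), and Fisher-exact gene-set
    enrichment with multiple-testing corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
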