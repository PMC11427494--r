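#!/usr/bin/env Rscript

# Stage 1 — simulate every input of the analysis with known ground truth.
#
# The study design being emulated: adult SMA patients (SMN1 absent, so all
# SMN reads come from SMN2) sequenced at baseline (T0) and after ten months
# of nusinersen (T10), against healthy controls; paired-end 2x100 bp mRNA
# reads; negative-binomial count matrices for long-RNA and small-RNA
# feature classes at 10-vs-10 (T0) and 10-vs-6 (T10) sample sizes, with
# planted differential expression of which half resolves under treatment.

suppressMessages(library(smaseq))

seed <- 20260925L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating SMN fragments (2000 per time point, exon-7 inclusion ",
        "0.3 at T0 rising to 0.6 at T10 under treatment)...")
sim_t0 <- make_smn_fragments("sma", 2000L, 0.3, seed = seed + 1L)
sim_t10 <- make_smn_fragments("sma", 2000L, 0.6, seed = seed + 2L)
write_fastq_pairs(sim_t0$reads, file.path(out, "smn_t0_R1.fastq"),
                  file.path(out, "smn_t0_R2.fastq"))
write_fastq_pairs(sim_t10$reads, file.path(out, "smn_t10_R1.fastq"),
                  file.path(out, "smn_t10_R2.fastq"))
jsonlite::write_json(
  list(t0 = as.list(sim_t0$truth$planted_counts),
       t10 = as.list(sim_t10$truth$planted_counts)),
  file.path(out, "smn_truth.json"), auto_unbox = TRUE, pretty = TRUE)

message("Simulating per-patient normalized SMN2 expression (6 paired ",
        "patients, ~1.7x mean increase at T10)...")
smn2 <- smaseq:::with_seed(seed + 3L, data.frame(
  patient = sprintf("SMA_%02d", 1:6),
  smn2_t0 = rnbinom(6L, mu = 100, size = 20),
  smn2_t10 = rnbinom(6L, mu = 170, size = 20)))
write.table(smn2, file.path(out, "smn2_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulating count matrices (lnRNA 1200 features, sRNA 300; ",
        "NB dispersion 0.1, baseline mean 200)...")
plant <- function(n_planted, prefix, lfc, frac_up = 0.8) {
  ids <- sprintf("%s%04d", prefix, seq_len(n_planted))
  n_up <- round(n_planted * frac_up)
  setNames(c(rep(lfc, n_up), rep(-lfc, n_planted - n_up)), ids)
}
eff_genes <- plant(60L, "gene", 2)
eff_mirs <- plant(30L, "mir", 1)
halve <- function(eff) eff[seq_len(floor(length(eff) / 2))]

specs <- list(
  genes_t0 = list(n = 1200L, sizes = c(10L, 10L), eff = eff_genes,
                  class = "lnRNA", off = 10L),
  genes_t10 = list(n = 1200L, sizes = c(10L, 6L), eff = halve(eff_genes),
                   class = "lnRNA", off = 11L),
  mirna_t0 = list(n = 300L, sizes = c(10L, 10L), eff = eff_mirs,
                  class = "sRNA", off = 12L),
  mirna_t10 = list(n = 300L, sizes = c(10L, 6L), eff = halve(eff_mirs),
                   class = "sRNA", off = 13L)
)
for (nm in names(specs)) {
  s <- specs[[nm]]
  sim <- make_count_matrix(s$n, s$sizes, s$eff, baseline_mean = 200,
                           dispersion = 0.1, feature_class = s$class,
                           seed = seed + s$off)
  write_count_tsv(sim$matrix, file.path(out, paste0(nm, "_counts.tsv")))
  write.table(data.frame(sample = names(sim$matrix$groups),
                         group = unname(sim$matrix$groups)),
              file.path(out, paste0(nm, "_groups.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(s$eff),
                       file.path(out, paste0(nm, "_truth.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  message("  ", nm, ": ", s$n, " features, ", sum(s$sizes), " samples, ",
          length(s$eff), " planted effects")
}

message("Done. Inputs written under ", out)
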