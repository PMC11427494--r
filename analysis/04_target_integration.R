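#!/usr/bin/env Rscript

# Stage 4 — inverse-expression miRNA-target integration.
#
# Crosses significant up-miRNAs with significant down-genes (and vice
# versa), then keeps only pairs supported by the interaction database,
# labelled validated (experimental evidence, dominant) or predicted
# (>= min_predictors prediction algorithms).

suppressMessages(library(smaseq))

de_dir <- "results/de"
if (!file.exists(file.path(de_dir, "de_genes_t0.tsv"))) {
  stop("inputs missing; run analysis/03_differential_expression.R first")
}
out <- "results/integration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

genes <- read.delim(file.path(de_dir, "de_genes_t0.tsv"))
mirna <- read.delim(file.path(de_dir, "de_mirna_t0.tsv"))
pairs <- inverse_candidate_pairs(mirna, genes)
message(nrow(pairs), " inverse-expression candidate pairs from ",
        sum(mirna$significant), " significant miRNAs x ",
        sum(genes$significant), " significant genes")

# the simulated database knows a subset of the truly inverse pairs plus a
# trickle of spurious predictions
true_pairs <- head(pairs[, c("mirna", "gene")], 40L)
db <- make_interaction_db(unique(pairs$mirna), unique(pairs$gene),
                          true_pairs, validated_fraction = 0.4,
                          per_predictor_recall = 0.5,
                          false_link_rate = 0.002, seed = seed + 200L)
write.table(db$db, file.path(out, "interaction_db.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- annotate_pairs(pairs, db$db, min_predictors = 1L)
write.table(tab, file.path(out, "integration.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(tab), " supported pairs retained: ",
        sum(tab$label == "validated"), " validated, ",
        sum(tab$label == "predicted"), " predicted")
print(head(tab))
message("Done. Tables under ", out)
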