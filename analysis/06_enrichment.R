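#!/usr/bin/env Rscript

# Stage 6 — Fisher-exact gene-set enrichment of the significant genes.
#
# Writes a synthetic GMT (one pathway seeded with differentially expressed
# genes among random sets), reads it back through the package's GMT
# reader, and tests enrichment with hypergeometric upper-tail p-values plus
# Benjamini-Hochberg and Bonferroni corrections.

suppressMessages(library(smaseq))

de_dir <- "results/de"
if (!file.exists(file.path(de_dir, "de_genes_t0.tsv"))) {
  stop("inputs missing; run analysis/03_differential_expression.R first")
}
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

genes <- read.delim(file.path(de_dir, "de_genes_t0.tsv"))
universe <- genes$feature
query <- genes$feature[genes$significant]

gmt_path <- file.path(out, "synthetic_sets.gmt")
smaseq:::with_seed(seed + 400L, {
  planted <- unique(c(sample(query, min(20L, length(query))),
                      sample(universe, 10L)))
  sets <- c(list(planted_pathway = planted),
            setNames(lapply(1:5, function(i) sample(universe, 30L)),
                     sprintf("random_set_%d", 1:5)))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t")
  }, character(1)), gmt_path)
})

sets <- read_gmt(gmt_path)
res <- fisher_enrichment(query, universe, sets)
write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Enrichment over ", length(sets), " terms (query ", length(query),
        " of ", length(universe), " genes):")
print(res)
message("Done. Tables under ", out)
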