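#!/usr/bin/env Rscript
# Differential expression (PDAC vs CP) on the training cohort and the
# candidate filter: expressed in all specimens, mean normalized
# expression >= 50, |log2FC| > 1, p < 0.05.

suppressPackageStartupMessages(library(evmir))

counts <- read_counts("results/simdata/counts.tsv")
samples <- read_metadata("results/simdata/samples.csv", counts)
truth <- jsonlite::read_json("results/simdata/truth.json")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

ids <- samples$specimen_id[samples$cohort == "training"]
lab <- samples$diagnosis[match(ids, samples$specimen_id)]
norm <- normalize_counts(counts[, ids, drop = FALSE])

de <- de_table(counts[, ids, drop = FALSE], norm, lab, "PDAC", "CP")
de$passes_filter <- de$mirna_id %in%
  suppressWarnings(candidate_filter(de, filter_thresholds()))
write.table(de, "results/de/de_training.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cand <- de$mirna_id[de$passes_filter]
cat(sprintf("%d of %d miRNAs pass the diagnostic filter: %s\n",
            length(cand), nrow(de), paste(cand, collapse = ", ")))
cat(sprintf("planted pair among them: %s\n",
            all(c(truth$diag_up_mirna, truth$diag_down_mirna) %in% cand)))
top <- de[order(de$p_value), ][1:5, c("mirna_id", "mean_a", "mean_b",
                                      "log2fc", "p_value", "fdr")]
print(top, row.names = FALSE, digits = 3)
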