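#!/usr/bin/env Rscript
# Housekeeping-based normalization and principal components of the
# max-scaled profiles, per cohort. Writes per-specimen PC coordinates and
# reports how well PC1/PC2 separate PDAC from CP.

suppressPackageStartupMessages(library(evmir))

counts <- read_counts("results/simdata/counts.tsv")
samples <- read_metadata("results/simdata/samples.csv", counts)
dir.create("results/pca", showWarnings = FALSE, recursive = TRUE)

for (coh in c("training", "test")) {
  ids <- samples$specimen_id[samples$cohort == coh]
  norm <- normalize_counts(counts[, ids, drop = FALSE])
  cat(sprintf("%s cohort: %d housekeeping miRNAs, size factors %.0f-%.0f\n",
              coh, length(norm$housekeeping_ids),
              min(norm$size_factors), max(norm$size_factors)))
  scaled <- max_scale(norm)
  p <- pca_specimens(scaled, k = 2)
  df <- data.frame(specimen_id = rownames(p$coords),
                   PC1 = p$coords[, 1], PC2 = p$coords[, 2],
                   diagnosis = samples$diagnosis[match(rownames(p$coords),
                                                       samples$specimen_id)])
  write.table(df, sprintf("results/pca/pca_%s.tsv", coh), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * p$var_frac[1], 100 * p$var_frac[2]))
  two <- df[df$diagnosis %in% c("PDAC", "CP"), ]
  cat(sprintf("  PC1 separation (PDAC vs CP AUC): %.3f\n",
              max(auc(two$PC1, two$diagnosis, "PDAC"),
                  1 - auc(two$PC1, two$diagnosis, "PDAC"))))
}
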