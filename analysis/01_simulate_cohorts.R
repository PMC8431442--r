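#!/usr/bin/env Rscript
# Generate the synthetic study: a training cohort (30 PDAC / 18 CP) and a
# test cohort (27 PDAC / 15 CP, plus 12 healthy controls), one shared
# biology (same planted markers), with overall survival tied to the
# planted metastasis ratio. Writes the count matrix, specimen metadata and
# the planted-truth sidecar under results/simdata/.

suppressPackageStartupMessages(library(evmir))

seed <- 20260930 %% 100000
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_pdac = 57L, n_cp = 33L, n_healthy = 12L, seed = seed)
cohort <- simulate_cohort(cfg)
samples <- assign_cohorts(cohort$samples, n_pdac_train = 30L,
                          n_cp_train = 18L, n_healthy_train = 0L)

norm <- normalize_counts(cohort$counts)
met_ratio <- norm$values[cohort$truth$met_up_mirna, ] /
  norm$values[cohort$truth$met_down_mirna, ]
samples <- simulate_survival(samples, met_ratio, cfg)

write_counts(cohort$counts, file.path(out, "counts.tsv"))
write_metadata(samples, file.path(out, "samples.csv"))
write_truth(cohort$truth, file.path(out, "truth.json"))

cat(sprintf("cohort: %d miRNAs x %d specimens (%d training, %d test)\n",
            nrow(cohort$counts), ncol(cohort$counts),
            sum(samples$cohort == "training"),
            sum(samples$cohort == "test")))
cat(sprintf("planted diagnostic pair: %s (up in PDAC) / %s (up in CP)\n",
            cohort$truth$diag_up_mirna, cohort$truth$diag_down_mirna))
cat(sprintf("planted metastasis pair: %s / %s\n",
            cohort$truth$met_up_mirna, cohort$truth$met_down_mirna))
cat(sprintf("survival: %d PDAC patients, %d deaths observed\n",
            sum(samples$diagnosis == "PDAC"),
            sum(samples$os_event == 1, na.rm = TRUE)))
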