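#!/usr/bin/env Rscript
# Discrete Bayesian network over median-discretized training expression
# plus the three pathology indicators (cancer, pancreatitis, metastasis):
# tabu-search structure learning under BIC, then extraction of the
# cause/consequence subnetwork around the cancer node.

suppressPackageStartupMessages(library(evmir))

counts <- read_counts("results/simdata/counts.tsv")
samples <- read_metadata("results/simdata/samples.csv", counts)
truth <- jsonlite::read_json("results/simdata/truth.json")
dir.create("results/bn", showWarnings = FALSE, recursive = TRUE)

ids <- samples$specimen_id[samples$cohort == "training"]
norm <- normalize_counts(counts[, ids, drop = FALSE])

# node pool: the ratio pool plus the most variable miRNAs, 27 + 3 nodes
lab <- samples$diagnosis[match(ids, samples$specimen_id)]
de <- de_table(counts[, ids, drop = FALSE], norm, lab, "PDAC", "CP")
pool <- suppressWarnings(candidate_filter(de, filter_thresholds(),
                                          mode = "metastatic"))
vr <- apply(norm$values, 1, var)
pool <- head(unique(c(pool, rownames(norm$values)[order(-vr)])), 27)

disc <- add_pathology_nodes(discretize_by_median(norm$values[pool, ]),
                            samples)
dag <- tabu_search(disc)
edges <- dag_edges(dag)
write.table(edges, "results/bn/edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(c("digraph bn {",
             sprintf("  \"%s\" -> \"%s\";", edges$from, edges$to), "}"),
           "results/bn/network.dot")

cat(sprintf("learned network: %d nodes, %d edges, BIC %.1f\n",
            length(dag$nodes), nrow(edges), dag$score))
for (node in c("cancer", "pancreatitis", "metastasis")) {
  nb <- neighborhood(dag, node)
  cat(sprintf("%s: causes {%s} consequences {%s}\n", node,
              paste(nb$causes, collapse = ", "),
              paste(nb$consequences, collapse = ", ")))
}
nb <- neighborhood(dag, "cancer")
cat(sprintf("planted up-in-PDAC miRNA %s adjacent to cancer: %s\n",
            truth$diag_up_mirna,
            truth$diag_up_mirna %in% c(nb$causes, nb$consequences)))
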