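Package: evmir
Title: Blood Small-EV miRNA Ratio Biomarkers for Pancreatic Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discriminating pancreatic ductal
    adenocarcinoma (PDAC) from chronic pancreatitis (CP) using blood
    small-extracellular-vesicle miRNA sequencing counts. Implements
    housekeeping-based 75th-percentile normalization, differential-expression
    candidate filtering, exhaustive ratio (quotient) biomarker search by ROC
    AUC, a two-threshold diagnostic rule combining a miRNA ratio with serum
    CA19-9, discrete Bayesian-network structure learning (tabu search, BIC)
    with cause/consequence subnetwork extraction around pathology nodes, and
    a metastasis/survival subgroup analysis. Includes a negative-binomial
    synthetic-cohort generator with planted markers for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, survival
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
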