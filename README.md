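# evmir

Blood small-extracellular-vesicle (EV) miRNA analysis for the differential
diagnosis of pancreatic ductal adenocarcinoma (PDAC) versus chronic
pancreatitis (CP), for bioinformaticians and biostatisticians working with
liquid-biopsy small-RNA-seq counts.

Imaging and serum CA19-9 separate PDAC from CP poorly. This package
implements a ratio ("joint marker") strategy over blood small-EV miRNA
counts, end to end:

1. **Normalization** — housekeeping miRNAs are those with ≥ 1 read in
   every specimen; the per-specimen size factor is the 75th percentile of
   their counts, and normalized expression is `reads / size factor`.
2. **Candidate filtering** — expressed in all specimens, mean normalized
   expression ≥ 50, |log2FC| > 1, p < 0.05 (Welch t on log2 counts, with a
   moderated empirical-Bayes variant; BH FDR optional).
3. **Ratio search** — for a top numerator miRNA, the AUC of the quotient
   x = numerator/denominator is evaluated exhaustively over the candidate
   pool, with the Mann–Whitney estimator
   AUC = P(x_case > x_control) + ½·P(tie).
4. **Decision rules** — ratio rule: Tumor iff x ≥ cutoff; combined rule
   with serum CA19-9: f(x, y) = Benign iff x < x₀ and y < y₀ (defaults
   x₀ = 0.06, y₀ = 300 U/ml), Tumor otherwise. Discovery uses training
   specimens only; the frozen rule is evaluated on the test cohort with
   sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
5. **Bayesian network** — median-discretized profiles plus `cancer`,
   `pancreatitis` and `metastasis` indicator nodes; BIC-scored structure
   learning by deterministic tabu search (exhaustively verified on ≤ 4
   nodes), and cause/consequence subnetwork extraction around any node.
6. **Metastasis & survival** — the same machinery within PDAC (M1 vs M0,
   no fold-change clause), a median-split log-rank survival filter,
   and Kaplan–Meier stratification of the discovered ratio at its cutoff.

Because the study's sequencing data are unreleased, `simulate_cohort()`
generates negative-binomial cohorts with the study's design (cohort
sizes, CA19-9 moments, 334 miRNAs, planted diagnostic and metastasis
ratio pairs, survival tied to the metastasis marker), so every claim is
testable as a recovery or calibration property. See the methods vignette
(`vignettes/evmir-methods.Rmd`) for models, conventions and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (each writes tables under `results/`):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/04_ratio_biomarker.R
```

prints, after discovery on the training cohort and frozen evaluation on
the test cohort:

```
cohort: 334 miRNAs x 102 specimens (48 training, 54 test)
planted diagnostic pair: mir-120 (up in PDAC) / mir-063 (up in CP)

Blood small-EV miRNA pipeline report
  ratio marker: mir-120 / mir-063 (cutoff 0.9941, training AUC 1.000)
  training cohort (ratio AUC 1.000):
    ratio rule:    sens 100.0%  spec 100.0%
    combined rule: sens 100.0%  spec 100.0%
  test cohort (ratio AUC 1.000):
    ratio rule:    sens 100.0%  spec 100.0%
    combined rule: sens 100.0%  spec 100.0%
```

The search recovered exactly the planted pair (mir-120 up in PDAC,
mir-063 up in CP), chose a Youden cutoff on the training specimens only,
and the frozen rule classified the held-out test cohort perfectly — at
the planted effect size (log2FC = 2, dispersion 0.1) the ratio separates
the groups completely, matching the closed-form AUC
Φ(Δ/(σ√2)) ≈ 1. `analysis/05_bayesian_network.R` then places both
planted miRNAs adjacent to the `cancer` node, and
`analysis/06_metastasis_survival.R` stratifies survival by the recovered
metastasis ratio (median OS 73 vs 318 days, log-rank p = 3.8e-06).

In evaluation-only mode (`pipeline_config(marker = ratio_marker(...))`)
the pipeline skips discovery and applies a published marker — e.g. the
miR-95-3p/miR-26b-5p quotient at cutoff 0.06 with CA19-9 at 300 U/ml —
to your own count matrix and metadata (`read_counts()`,
`read_metadata()`).

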