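test_that("AUC enumerates case/control pairs with half-weight ties", {
  expect_equal(auc(c(4, 5, 6, 1, 2, 3), rep(c("x", "y"), each = 3),
                   case = "x"), 1.0)
  expect_equal(auc(c(1, 3, 2, 4), c("x", "x", "y", "y"), case = "x"), 0.25)
  expect_equal(auc(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3),
                   case = "x"), 0.5)
  expect_error(auc(1:3, rep("x", 3), case = "x"), "nonempty")
})

test_that("rank-based AUC equals brute-force pair enumeration", {
  set.seed(51)
  for (r in 1:200) {
    n <- sample(4:30, 1)
    v <- sample(c(rnorm(n), round(rnorm(n), 0)), n)  # mix in ties
    lab <- sample(c("case", "ctrl"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc(v, lab, case = "case"), auc_pairs(v, lab, "case"),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are monotone and trapezoid area equals the AUC", {
  set.seed(52)
  for (r in 1:20) {
    v <- round(rnorm(20), 1)
    lab <- rep(c("case", "ctrl"), each = 10)
    roc <- roc_curve(v, lab, case = "case")
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(area, auc(v, lab, case = "case"), tolerance = 1e-12)
  }
  one <- roc_curve(c(2, 1), c("case", "ctrl"), case = "case")
  expect_equal(one$fpr, c(0, 0, 1))
  expect_equal(one$tpr, c(0, 1, 1))
})

test_that("AUC is invariant under strictly increasing transforms and flips under negation", {
  set.seed(53)
  v <- rexp(24); lab <- rep(c("case", "ctrl"), 12)
  a <- auc(v, lab, case = "case")
  expect_equal(auc(log(v), lab, case = "case"), a, tolerance = 1e-12)
  expect_equal(auc(v^3, lab, case = "case"), a, tolerance = 1e-12)
  expect_equal(auc(-v, lab, case = "case"), 1 - a, tolerance = 1e-12)
})

test_that("single-marker ranking sorts by AUC with ID tie-break", {
  m <- matrix(c(10, 20, 1, 2,
                5, 5, 5, 5,
                2, 1, 20, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "flat", "down"), paste0("s", 1:4)))
  lab <- c("PDAC", "PDAC", "CP", "CP")
  rk <- rank_single_markers(m, lab, c("down", "up", "flat"))
  expect_equal(rk$mirna_id, c("up", "flat", "down"))
  expect_equal(rk$auc, c(1, 0.5, 0))
  expect_error(rank_single_markers(m, lab, character(0)), "empty")
})

test_that("a constant denominator leaves the numerator's AUC unchanged", {
  ch <- small_cohort(seed = 54L)
  norm <- normalize_counts(ch$counts)
  x <- norm$values
  const <- matrix(rep(1, ncol(x)), nrow = 1,
                  dimnames = list("const", colnames(x)))
  xx <- rbind(x, const)
  lab <- ch$samples$diagnosis
  num <- ch$truth$diag_up_mirna
  rs <- ratio_search(xx, lab, num, c("const"))
  expect_equal(rs$auc, auc(x[num, ], lab, case = "PDAC"), tolerance = 1e-12)
  # the numerator never appears as its own denominator
  rs2 <- ratio_search(xx, lab, num, c(num, "const"))
  expect_false(num %in% rs2$denominator)
  expect_error(ratio_search(xx, lab, num, num), "no candidate")
})

test_that("specimens with zero denominator values are excluded, not imputed", {
  m <- matrix(c(8, 6, 4, 2,
                2, 0, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("num", "den"), paste0("s", 1:4)))
  lab <- c("PDAC", "PDAC", "CP", "CP")
  rs <- ratio_search(m, lab, "num", "den")
  expect_equal(rs$n_evaluated, 3L)
  expect_equal(rs$auc, auc(c(4, 4, 2), c("PDAC", "CP", "CP"),
                           case = "PDAC"))
})

test_that("youden cutoff maximizes sensitivity + specificity - 1", {
  expect_equal(choose_cutoff(strategy = "fixed", cutoff = 0.06), 0.06)
  v <- c(10, 11, 1, 2); lab <- c("PDAC", "PDAC", "CP", "CP")
  cut <- choose_cutoff(v, lab, "youden")
  expect_gt(cut, 2); expect_lt(cut, 10)
  expect_equal(mean(v[lab == "PDAC"] >= cut), 1)
  expect_equal(mean(v[lab == "CP"] < cut), 1)

  # brute-force scan over a dense grid reproduces the maximized index
  set.seed(55)
  for (r in 1:20) {
    v <- round(rexp(12), 1)
    lab <- sample(rep(c("PDAC", "CP"), 6))
    cut <- choose_cutoff(v, lab, "youden")
    jj <- function(c0) mean(v[lab == "PDAC"] >= c0) +
      mean(v[lab == "CP"] < c0) - 1
    grid <- sort(unique(c(v, v - 1e-6, v + 1e-6)))
    expect_equal(jj(cut), max(sapply(grid, jj)), tolerance = 1e-12)
  }
})

test_that("ratio and combined rules respect their strict boundaries", {
  expect_equal(classify_ratio(c(0.05, 0.07, 0.06)),
               c("Benign", "Tumor", "Tumor"))
  rule <- combined_rule()
  expect_equal(classify_combined(0.05, 200, rule), "Benign")
  expect_equal(classify_combined(0.05, 400, rule), "Tumor")
  expect_equal(classify_combined(0.06, 300, rule), "Tumor")
  expect_warning(out <- classify_combined(c(0.05, 0.07), c(NA, NA), rule),
                 "missing CA19-9")
  expect_equal(out, c("Benign", "Tumor"))
})

test_that("the combined rule's Tumor region contains the ratio rule's", {
  set.seed(56)
  x <- rexp(300, 10); y <- rexp(300, 1 / 200)
  r_call <- classify_ratio(x)
  c_call <- classify_combined(x, y)
  expect_true(all(c_call[r_call == "Tumor"] == "Tumor"))
})

test_that("confusion metrics reproduce the printed sensitivity/specificity arithmetic", {
  pred <- c(rep("Tumor", 26), rep("Benign", 4), rep("Benign", 18))
  truth <- c(rep("PDAC", 30), rep("CP", 18))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 86.7)
  expect_equal(cm$specificity, 100)
  cm2 <- confusion_metrics(
    c(rep("Tumor", 22), rep("Benign", 5), rep("Tumor", 1), rep("Benign", 14)),
    c(rep("PDAC", 27), rep("CP", 15)))
  expect_equal(cm2$sensitivity, 81.5)
  expect_equal(cm2$specificity, 93.3)
  perfect <- confusion_metrics(c("Tumor", "Benign"), c("PDAC", "CP"))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$tp + perfect$fn + perfect$tn + perfect$fp, 2)
  expect_error(confusion_metrics(c("weird"), c("PDAC")), "unknown")
})

test_that("metastasis discovery recovers the planted pair and demands events", {
  ch <- simulate_cohort(sim_config(n_pdac = 30L, n_cp = 10L, seed = 57L))
  norm <- normalize_counts(ch$counts)
  rv <- norm$values[ch$truth$met_up_mirna, ] /
    norm$values[ch$truth$met_down_mirna, ]
  samples <- simulate_survival(ch$samples, rv, ch$config)
  res <- metastasis_candidates(ch$counts, norm, samples)
  expect_true(!is.null(res$best_pair))
  expect_equal(res$best_pair$numerator_id, ch$truth$met_up_mirna)
  expect_equal(res$best_pair$denominator_id, ch$truth$met_down_mirna)

  no_ev <- samples; no_ev$os_event[no_ev$diagnosis == "PDAC"] <- 0L
  expect_error(metastasis_candidates(ch$counts, norm, no_ev), "events")
})
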