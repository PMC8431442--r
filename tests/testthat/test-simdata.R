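test_that("the same config and seed reproduce the cohort exactly", {
  a <- small_cohort(seed = 4L)
  b <- small_cohort(seed = 4L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(seed = 5L)
  expect_false(identical(a$counts, c$counts))
})

test_that("configs are validated", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_mirna = 8), "n_mirna")
  expect_error(sim_config(frac_metastatic = 1.2), "frac_metastatic")
})

test_that("no planted effect means an all-zero truth map", {
  ch <- small_cohort(seed = 2L, diag_log2fc = 0, met_log2fc = 0)
  expect_true(all(ch$truth$log2fc == 0))
  expect_true(all(ch$truth$met_log2fc == 0))
})

test_that("counts are nonnegative integers and the boosted pool never hits zero", {
  ch <- small_cohort(seed = 3L)
  expect_true(is.integer(ch$counts))
  expect_true(all(ch$counts >= 0))
  expect_true(all(ch$counts[ch$truth$housekeeping_pool, ] >= 1))
  expect_true(all(c(ch$truth$diag_up_mirna, ch$truth$diag_down_mirna,
                    ch$truth$met_up_mirna, ch$truth$met_down_mirna) %in%
                    rownames(ch$counts)))
})

test_that("metastasis labels exist only for PDAC and match the configured fraction", {
  ch <- small_cohort(seed = 6L)
  s <- ch$samples
  expect_true(all(is.na(s$metastasis[s$diagnosis != "PDAC"])))
  expect_equal(sum(s$metastasis == "M1", na.rm = TRUE),
               round(0.4 * sum(s$diagnosis == "PDAC")))
})

test_that("planted fold change matches an independent negative-binomial sampler", {
  # spec'd conditions: PDAC/CP 30/18, log2fc 2, dispersion 0.1, sigma 0.25
  cfg <- sim_config(n_pdac = 30L, n_cp = 18L, diag_log2fc = 2,
                    dispersion = 0.1, libsize_sigma = 0.25, seed = 1L)
  ch <- simulate_cohort(cfg)
  up <- ch$truth$diag_up_mirna
  obs_ratio <- mean(ch$counts[up, ch$samples$diagnosis == "PDAC"]) /
    mean(ch$counts[up, ch$samples$diagnosis == "CP"])

  # straight-line oracle: draw the same design 10,000 times from rnbinom
  # directly (no package code) and band the mean ratio
  set.seed(99)
  reps <- replicate(10000, {
    sp <- rlnorm(30, 0, 0.25); sc <- rlnorm(18, 0, 0.25)
    mean(rnbinom(30, mu = 1e4 * sp * 4, size = 10)) /
      mean(rnbinom(18, mu = 1e4 * sc, size = 10))
  })
  band <- quantile(reps, c(0.025, 0.975))
  expect_gt(obs_ratio, band[1])
  expect_lt(obs_ratio, band[2])
})

test_that("CA19-9 draws match the configured moments", {
  cfg <- sim_config(n_pdac = 10000L, n_cp = 2L, seed = 8L)
  ch <- simulate_cohort(cfg)
  x <- ch$samples$ca199_u_ml[ch$samples$diagnosis == "PDAC"]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 560.7), 3 * se)
})

test_that("survival honors degenerate censoring and hazard direction", {
  ch <- small_cohort(seed = 9L)
  marker <- setNames(rep(1, nrow(ch$samples)), ch$samples$specimen_id)

  cfg0 <- sim_config(n_pdac = 12L, n_cp = 10L, n_mirna = 60L,
                     censor_max = 1e-9, seed = 9L)
  s0 <- simulate_survival(ch$samples, marker, cfg0)
  pdac <- s0$diagnosis == "PDAC"
  expect_true(all(s0$os_event[pdac] == 0))
  expect_true(all(s0$os_days[pdac] < 1e-8))

  # strong positive log-HR: higher-marker group dies sooner in >= 95% of reps
  worse <- 0L
  for (r in 1:100) {
    chr <- small_cohort(seed = 100L + r)
    m <- setNames(ifelse(seq_len(nrow(chr$samples)) %% 2 == 0, 4, 0.25),
                  chr$samples$specimen_id)
    cfg <- sim_config(n_pdac = 12L, n_cp = 10L, n_mirna = 60L,
                      surv_log_hr = 2, censor_max = 1e5, seed = 100L + r)
    sr <- simulate_survival(chr$samples, m, cfg)
    pd <- sr$diagnosis == "PDAC"
    hi <- m[sr$specimen_id] > 1
    if (median(sr$os_days[pd & hi]) < median(sr$os_days[pd & !hi]))
      worse <- worse + 1L
  }
  expect_gte(worse / 100, 0.95)
})

test_that("survival rejects invalid hazards and markers", {
  ch <- small_cohort(seed = 10L)
  cfg <- ch$config
  cfg$surv_base_hazard <- 0
  expect_error(simulate_survival(ch$samples, rep(1, nrow(ch$samples)), cfg),
               "hazard")
  bad <- rep(1, nrow(ch$samples))
  bad[ch$samples$diagnosis == "PDAC"][1] <- 0
  expect_error(simulate_survival(ch$samples, bad, ch$config), "positive")
})

test_that("analytic ratio AUC follows the normal closed form", {
  expect_equal(analytic_ratio_auc(0, 1), 0.5)
  expect_equal(analytic_ratio_auc(1e9, 0.3), 1.0)
  expect_equal(analytic_ratio_auc(sqrt(2) * 0.7, 0.7), pnorm(1))
  expect_error(analytic_ratio_auc(1, 0), "sigma")
})

test_that("a null cohort yields no FDR-significant candidates in nearly all runs", {
  clean <- 0L; n_runs <- 30L
  for (r in seq_len(n_runs)) {
    ch <- simulate_cohort(sim_config(n_pdac = 15L, n_cp = 12L,
                                     n_mirna = 200L, diag_log2fc = 0,
                                     met_log2fc = 0, seed = 500L + r))
    norm <- normalize_counts(ch$counts)
    de <- de_table(ch$counts, norm, ch$samples$diagnosis, "PDAC", "CP")
    cand <- suppressWarnings(
      candidate_filter(de, filter_thresholds(use_fdr = TRUE),
                       mode = "metastatic"))
    if (length(cand) == 0L) clean <- clean + 1L
  }
  expect_gte(clean / n_runs, 0.95)
})
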