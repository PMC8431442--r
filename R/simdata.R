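#' Configuration for the synthetic blood small-EV miRNA cohort generator
#'
#' Defaults emulate the training-cohort design of the study this package
#' models: 30 PDAC and 18 chronic-pancreatitis (CP) specimens, 40% of PDAC
#' metastatic, 334 miRNAs (so that adding the three pathology indicators
#' yields a 337-node network), serum CA19-9 with PDAC mean 560.7 and SD
#' 496.7 U/ml, and negative-binomial counts with specimen-level library-size
#' variation.
#'
#' @param n_pdac,n_cp,n_healthy group sizes (specimens).
#' @param n_mirna number of miRNAs (>= 10).
#' @param frac_metastatic fraction of PDAC specimens labeled M1.
#' @param baseline_log10_range range (log10 units) of the log-uniform bulk
#'   baseline mean counts.
#' @param dominance_log10 extra abundance (log10 units) given to the
#'   top-abundance decile, emulating the dominance of a few miRNAs in
#'   plasma small-RNA libraries; this decile is the guaranteed
#'   housekeeping pool.
#' @param libsize_sigma SD of the log-normal specimen library-size factor.
#' @param dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2); must be > 0.
#' @param diag_log2fc planted diagnostic effect (log2): one miRNA is raised
#'   by this amount in PDAC, another in CP.
#' @param met_log2fc planted metastasis effect (log2): within PDAC, one
#'   miRNA is raised and one lowered by this amount in M1 specimens.
#' @param ca199_pdac_mean,ca199_pdac_sd,ca199_cp_mean,ca199_cp_sd serum
#'   CA19-9 moments (U/ml) per diagnosis group (log-normal, moment-matched).
#' @param cea_pdac_mean,cea_pdac_sd serum CEA moments (ng/ml) for PDAC.
#' @param surv_base_hazard baseline death hazard (1/day) at marker value 1.
#' @param surv_log_hr log hazard ratio per unit natural-log of the marker;
#'   the default 0.25 makes the planted metastasis ratio (a 16-fold
#'   M1-vs-M0 separation at `met_log2fc = 2`) carry a roughly two-fold
#'   hazard ratio, the order seen between metastatic and nonmetastatic
#'   pancreatic cancer.
#' @param censor_max upper bound (days) of the uniform censoring time.
#' @param seed integer global seed; all sub-streams derive from it via
#'   [stream_seed()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pdac = 30L, n_cp = 18L, n_healthy = 0L,
                       n_mirna = 334L, frac_metastatic = 0.4,
                       baseline_log10_range = c(-1, 3.8),
                       dominance_log10 = 2,
                       libsize_sigma = 0.25, dispersion = 0.1,
                       diag_log2fc = 2, met_log2fc = 2,
                       ca199_pdac_mean = 560.7, ca199_pdac_sd = 496.7,
                       ca199_cp_mean = 24, ca199_cp_sd = 15,
                       cea_pdac_mean = 5.5, cea_pdac_sd = 4.0,
                       surv_base_hazard = 1 / 365, surv_log_hr = 0.25,
                       censor_max = 1095, seed = 1L) {
  cfg <- list(n_pdac = as.integer(n_pdac), n_cp = as.integer(n_cp),
              n_healthy = as.integer(n_healthy),
              n_mirna = as.integer(n_mirna),
              frac_metastatic = frac_metastatic,
              baseline_log10_range = baseline_log10_range,
              dominance_log10 = dominance_log10,
              libsize_sigma = libsize_sigma, dispersion = dispersion,
              diag_log2fc = diag_log2fc, met_log2fc = met_log2fc,
              ca199_pdac_mean = ca199_pdac_mean,
              ca199_pdac_sd = ca199_pdac_sd,
              ca199_cp_mean = ca199_cp_mean, ca199_cp_sd = ca199_cp_sd,
              cea_pdac_mean = cea_pdac_mean, cea_pdac_sd = cea_pdac_sd,
              surv_base_hazard = surv_base_hazard,
              surv_log_hr = surv_log_hr, censor_max = censor_max,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pdac >= 0, cfg$n_cp >= 0, cfg$n_healthy >= 0)
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$n_mirna < 10L)
    stop("n_mirna must be >= 10 (4 planted markers plus a housekeeping pool)")
  if (cfg$frac_metastatic < 0 || cfg$frac_metastatic > 1)
    stop("frac_metastatic must lie in [0, 1]")
  if (cfg$libsize_sigma < 0) stop("libsize_sigma must be >= 0")
  if (length(cfg$baseline_log10_range) != 2L ||
      diff(cfg$baseline_log10_range) <= 0)
    stop("baseline_log10_range must be an increasing pair")
  invisible(cfg)
}

# log-normal parameters matched to a target arithmetic mean and SD
lnorm_match <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a blood small-EV miRNA cohort with planted markers
#'
#' Counts for miRNA m in specimen j are negative-binomial with mean
#' `a_m * s_j * 2^effect(m, j)`: `a_m` is a log-uniform baseline (the
#' top-abundance decile receives an extra `dominance_log10` decades, so a
#' small set of miRNAs dominates the library as in real plasma small-RNA
#' data), `s_j` is a log-normal library-size factor, and `effect` carries
#' the planted group effects. Four distinct planted markers are drawn from
#' the upper half of the dominant decile: a diagnostic up-in-PDAC miRNA, an
#' up-in-CP miRNA, and a metastasis pair (up/down in M1 within PDAC). The
#' dominant decile is floored at one read in every specimen, so the
#' housekeeping rule (>= 1 read everywhere) always has a nonempty pool.
#' Serum CA19-9 and CEA are log-normal with group moments matched to the
#' configured mean/SD. `round(frac_metastatic * n_pdac)` PDAC specimens are
#' labeled M1. The draw is fully determined by `config$seed` via named
#' sub-streams (baselines, counts, clinical).
#'
#' @param config a [sim_config()].
#' @return list of class `ev_cohort` with elements `counts` (integer
#'   matrix, miRNA x specimen), `samples` (data.frame: specimen_id,
#'   diagnosis, metastasis, ca199_u_ml, cea_ng_ml), `truth` (planted roles
#'   and per-miRNA true log2 fold changes), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n_spec <- config$n_pdac + config$n_cp + config$n_healthy
  if (n_spec < 2L) stop("need at least 2 specimens")

  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
  diagnosis <- rep(c("PDAC", "CP", "healthy"),
                   c(config$n_pdac, config$n_cp, config$n_healthy))
  specimen_ids <- paste0(c("P", "C", "H")[match(diagnosis,
                                                c("PDAC", "CP", "healthy"))],
                         unlist(lapply(c(config$n_pdac, config$n_cp,
                                         config$n_healthy), seq_len)))

  # --- baselines and planted roles (stream: baselines) -------------------
  set.seed(stream_seed(config$seed, "baselines"))
  lo <- config$baseline_log10_range[1]; hi <- config$baseline_log10_range[2]
  log10_a <- stats::runif(config$n_mirna, lo, hi)
  n_pool <- max(4L, ceiling(config$n_mirna / 10))
  pool <- order(log10_a, decreasing = TRUE)[seq_len(n_pool)]
  log10_a[pool] <- log10_a[pool] + config$dominance_log10
  upper_half <- pool[seq_len(max(4L, floor(n_pool / 2)))]  # pool is sorted by abundance
  planted <- sample(upper_half, 4L)
  diag_up <- mirna_ids[planted[1]]; diag_down <- mirna_ids[planted[2]]
  met_up <- mirna_ids[planted[3]]; met_down <- mirna_ids[planted[4]]

  # --- clinical covariates (stream: clinical) ----------------------------
  set.seed(stream_seed(config$seed, "clinical"))
  metastasis <- rep(NA_character_, n_spec)
  is_pdac <- diagnosis == "PDAC"
  n_m1 <- round(config$frac_metastatic * config$n_pdac)
  m1_idx <- sample(which(is_pdac), n_m1)
  metastasis[is_pdac] <- "M0"
  metastasis[m1_idx] <- "M1"
  ca199 <- numeric(n_spec)
  p_pdac <- lnorm_match(config$ca199_pdac_mean, config$ca199_pdac_sd)
  p_cp <- lnorm_match(config$ca199_cp_mean, config$ca199_cp_sd)
  p_h <- lnorm_match(10, 7)   # healthy controls: normal range, not modeled
  ca199[is_pdac] <- stats::rlnorm(sum(is_pdac), p_pdac$meanlog, p_pdac$sdlog)
  ca199[diagnosis == "CP"] <- stats::rlnorm(config$n_cp, p_cp$meanlog,
                                            p_cp$sdlog)
  ca199[diagnosis == "healthy"] <- stats::rlnorm(config$n_healthy,
                                                 p_h$meanlog, p_h$sdlog)
  cea <- numeric(n_spec)
  c_pdac <- lnorm_match(config$cea_pdac_mean, config$cea_pdac_sd)
  c_ben <- lnorm_match(2.5, 1.5)
  cea[is_pdac] <- stats::rlnorm(sum(is_pdac), c_pdac$meanlog, c_pdac$sdlog)
  cea[!is_pdac] <- stats::rlnorm(sum(!is_pdac), c_ben$meanlog, c_ben$sdlog)

  # --- counts (stream: counts) ------------------------------------------
  set.seed(stream_seed(config$seed, "counts"))
  s_j <- stats::rlnorm(n_spec, 0, config$libsize_sigma)
  log2_effect <- matrix(0, config$n_mirna, n_spec)
  log2_effect[planted[1], diagnosis == "PDAC"] <- config$diag_log2fc
  log2_effect[planted[2], diagnosis == "CP"] <- config$diag_log2fc
  m1 <- !is.na(metastasis) & metastasis == "M1"
  log2_effect[planted[3], m1] <- config$met_log2fc
  log2_effect[planted[4], m1] <- -config$met_log2fc
  mu <- (10^log10_a) %o% s_j * 2^log2_effect
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   config$n_mirna, n_spec,
                   dimnames = list(mirna_ids, specimen_ids))
  counts[pool, ] <- pmax(counts[pool, , drop = FALSE], 1L)
  storage.mode(counts) <- "integer"

  log2fc <- stats::setNames(numeric(config$n_mirna), mirna_ids)
  log2fc[planted[1]] <- config$diag_log2fc
  log2fc[planted[2]] <- -config$diag_log2fc
  met_fc <- stats::setNames(numeric(config$n_mirna), mirna_ids)
  met_fc[planted[3]] <- config$met_log2fc
  met_fc[planted[4]] <- -config$met_log2fc

  samples <- data.frame(specimen_id = specimen_ids, diagnosis = diagnosis,
                        metastasis = metastasis,
                        ca199_u_ml = ca199, cea_ng_ml = cea,
                        stringsAsFactors = FALSE)
  truth <- list(diag_up_mirna = diag_up, diag_down_mirna = diag_down,
                met_up_mirna = met_up, met_down_mirna = met_down,
                log2fc = log2fc, met_log2fc = met_fc,
                housekeeping_pool = mirna_ids[pool])
  structure(list(counts = counts, samples = samples, truth = truth,
                 config = config),
            class = "ev_cohort")
}

#' Assign training / test cohort labels
#'
#' Splits a simulated cohort's specimens into a training and a test cohort
#' per diagnosis group (specimens are exchangeable within group). Defaults
#' mirror the study design: 30 PDAC + 18 CP train, the remainder test.
#'
#' @param samples specimen metadata data.frame.
#' @param n_pdac_train,n_cp_train,n_healthy_train specimens of each
#'   diagnosis assigned to the training cohort (first rows per group).
#' @return `samples` with a `cohort` column ("training"/"test").
#' @export
assign_cohorts <- function(samples, n_pdac_train = 30L, n_cp_train = 18L,
                           n_healthy_train = 0L) {
  samples$cohort <- "test"
  for (g in c("PDAC", "CP", "healthy")) {
    k <- switch(g, PDAC = n_pdac_train, CP = n_cp_train,
                healthy = n_healthy_train)
    i <- which(samples$diagnosis == g)
    samples$cohort[utils::head(i, k)] <- "training"
  }
  samples
}

#' Simulate overall-survival outcomes tied to a marker
#'
#' Event times are exponential with hazard
#' `surv_base_hazard * exp(surv_log_hr * log(marker))`; censoring is uniform
#' on (0, censor_max]. Overall survival is the earlier of the two, with the
#' event flag set when death precedes censoring. Survival is generated only
#' for PDAC specimens (the diagnosis under study); other rows get NA.
#'
#' @param samples specimen metadata data.frame (needs specimen_id,
#'   diagnosis).
#' @param marker positive per-specimen marker values, named by specimen_id
#'   or aligned with `samples`; must be defined for every PDAC specimen.
#' @param config a [sim_config()] (uses surv_base_hazard, surv_log_hr,
#'   censor_max, seed).
#' @return `samples` with columns `os_days` and `os_event` (1 = death).
#' @export
simulate_survival <- function(samples, marker, config) {
  if (config$surv_base_hazard <= 0) stop("surv_base_hazard must be > 0")
  if (!is.null(names(marker)))
    marker <- marker[samples$specimen_id]
  if (length(marker) != nrow(samples))
    stop("marker must align with samples")
  pdac <- samples$diagnosis == "PDAC"
  if (any(!is.finite(marker[pdac]) | marker[pdac] <= 0))
    stop("marker must be positive and finite for every PDAC specimen")
  set.seed(stream_seed(config$seed, "survival"))
  n <- sum(pdac)
  hazard <- config$surv_base_hazard *
    exp(config$surv_log_hr * log(marker[pdac]))
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, config$censor_max)
  samples$os_days <- NA_real_
  samples$os_event <- NA_integer_
  samples$os_days[pdac] <- pmin(t_event, t_cens)
  samples$os_event[pdac] <- as.integer(t_event <= t_cens)
  samples
}

#' Closed-form AUC of a log-normal ratio marker
#'
#' If the log-ratio is normal in both groups with common SD `sigma_log` and
#' between-group mean difference `delta_log`, the ROC AUC is exactly
#' `pnorm(delta_log / (sigma_log * sqrt(2)))`. Used as the recovery target
#' for the ratio search on low-dispersion simulations, where the
#' negative-binomial log-ratio is approximately normal.
#'
#' @param delta_log between-group difference of mean log-ratio (natural
#'   log).
#' @param sigma_log common within-group SD of the log-ratio; must be > 0.
#' @return AUC in [0.5, 1] for nonnegative `delta_log`.
#' @export
analytic_ratio_auc <- function(delta_log, sigma_log) {
  if (!is.finite(sigma_log) || sigma_log <= 0)
    stop("sigma_log must be > 0")
  stats::pnorm(delta_log / (sigma_log * sqrt(2)))
}
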