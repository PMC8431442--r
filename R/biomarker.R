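#' Mann-Whitney ROC AUC
#'
#' Probability that a random case scores above a random control, with ties
#' counted 0.5 (two-sample U statistic / (n1*n0)). Orientation is fixed by
#' the declared case class; there is no automatic flipping, so a marker
#' lower in cases reports an AUC below 0.5.
#'
#' @param values finite per-specimen marker values.
#' @param labels per-specimen class labels.
#' @param case label of the positive (case) class.
#' @return AUC in [0, 1].
#' @export
auc <- function(values, labels, case = "PDAC") {
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  is_case <- labels == case
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  r <- rank(values)   # midranks handle ties as 0.5 pair weight
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps all distinct thresholds (predict case when value >= threshold)
#' and returns (1 - specificity, sensitivity) pairs from (0,0) to (1,1).
#' The trapezoidal area under these points equals the Mann-Whitney [auc()].
#'
#' @inheritParams auc
#' @return data.frame with columns fpr, tpr (both non-decreasing).
#' @export
roc_curve <- function(values, labels, case = "PDAC") {
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  is_case <- labels == case
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  o <- order(values, decreasing = TRUE)
  v <- values[o]; pos <- is_case[o]
  keep <- c(diff(v) != 0, TRUE)   # last index of each distinct value
  tpr <- c(0, cumsum(pos)[keep] / n1)
  fpr <- c(0, cumsum(!pos)[keep] / n0)
  data.frame(fpr = fpr, tpr = tpr)
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Rank candidate miRNAs by single-marker AUC
#'
#' @param norm `ev_norm` or normalized matrix.
#' @param labels per-specimen labels.
#' @param candidates candidate miRNA IDs (rows of the matrix).
#' @param case positive class label.
#' @return data.frame (mirna_id, auc) sorted by descending AUC, ties
#'   broken by miRNA ID.
#' @export
rank_single_markers <- function(norm, labels, candidates, case = "PDAC") {
  if (length(candidates) == 0L) stop("candidate set is empty")
  x <- norm_values(norm)
  stopifnot(all(candidates %in% rownames(x)))
  a <- vapply(candidates, function(m) auc(x[m, ], labels, case), numeric(1))
  out <- data.frame(mirna_id = candidates, auc = unname(a),
                    stringsAsFactors = FALSE)
  out[order(-out$auc, out$mirna_id), , drop = FALSE]
}

#' Exhaustive ratio (quotient) biomarker search for a fixed numerator
#'
#' For each candidate denominator d, evaluates the AUC of the per-specimen
#' quotient numerator/d. Specimens where a denominator's normalized value
#' is 0 are excluded from that denominator's evaluation (logged); the
#' numerator itself is never a denominator.
#'
#' @param norm `ev_norm` or normalized matrix.
#' @param labels per-specimen labels.
#' @param numerator_id the target miRNA.
#' @param candidates candidate denominators (the numerator, if present, is
#'   dropped).
#' @param case positive class label.
#' @return data.frame (numerator, denominator, auc, log_ratio_t,
#'   n_evaluated) sorted by descending AUC; exact AUC ties (common once
#'   the AUC saturates at 1 on small cohorts) are broken by the larger
#'   absolute Welch t of the log-ratio, then by denominator ID.
#' @export
ratio_search <- function(norm, labels, numerator_id, candidates,
                         case = "PDAC") {
  x <- norm_values(norm)
  stopifnot(numerator_id %in% rownames(x))
  candidates <- setdiff(candidates, numerator_id)
  if (length(candidates) == 0L) stop("no candidate denominators")
  stopifnot(all(candidates %in% rownames(x)))
  num <- x[numerator_id, ]
  is_case <- labels == case
  log_t <- function(v, grp) {
    ok <- v > 0 & is.finite(v)
    lv <- log(v[ok]); g <- grp[ok]
    if (length(unique(g)) < 2L) return(0)
    va <- stats::var(lv[g]); vb <- stats::var(lv[!g])
    se2 <- va / sum(g) + vb / sum(!g)
    if (!is.finite(se2) || se2 <= 0) return(0)
    (mean(lv[g]) - mean(lv[!g])) / sqrt(se2)
  }
  rows <- lapply(candidates, function(d) {
    den <- x[d, ]
    ok <- den > 0
    if (!all(ok))
      stage_log("ratio_search", "denominator %s: excluded %d specimen(s) %s",
                d, sum(!ok), "with zero normalized value")
    r <- num[ok] / den[ok]
    data.frame(numerator = numerator_id, denominator = d,
               auc = auc(r, labels[ok], case),
               log_ratio_t = log_t(r, is_case[ok]),
               n_evaluated = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc, -abs(out$log_ratio_t), out$denominator), ,
      drop = FALSE]
}

#' Choose a classification cutoff
#'
#' `fixed` returns the supplied cutoff unchanged. `youden` maximizes
#' sensitivity + specificity - 1 over the midpoints of consecutive
#' distinct values plus the two degenerate cutoffs (call everything /
#' nothing a case), with a case call when value >= cutoff; ties resolve
#' to the smaller cutoff.
#'
#' @param values per-specimen marker values.
#' @param labels per-specimen labels (ignored for `fixed`).
#' @param strategy "youden" or "fixed".
#' @param cutoff the fixed cutoff (required when strategy = "fixed").
#' @param case positive class label.
#' @return the chosen cutoff.
#' @export
choose_cutoff <- function(values, labels = NULL,
                          strategy = c("youden", "fixed"), cutoff = NULL,
                          case = "PDAC") {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (is.null(cutoff)) stop("fixed strategy needs a cutoff")
    return(cutoff)
  }
  is_case <- labels == case
  if (!any(is_case) || all(is_case)) stop("both classes must be nonempty")
  v <- sort(unique(values))
  if (length(v) < 2L) return(v[1])
  span <- v[length(v)] - v[1]
  cand <- c(v[1], (utils::head(v, -1) + utils::tail(v, -1)) / 2,
            v[length(v)] + span)
  j <- vapply(cand, function(c0) {
    mean(values[is_case] >= c0) + mean(values[!is_case] < c0) - 1
  }, numeric(1))
  cand[which.max(j)]   # which.max takes the first, i.e. smallest, maximizer
}

#' Classify by a ratio cutoff
#'
#' Benign when the ratio is strictly below the cutoff, Tumor otherwise
#' (the boundary value falls to Tumor).
#'
#' @param x nonnegative ratio value(s).
#' @param cutoff positive cutoff (diagnostic default 0.06).
#' @return character vector in {"Tumor", "Benign"}.
#' @export
classify_ratio <- function(x, cutoff = 0.06) {
  stopifnot(all(x >= 0, na.rm = TRUE), cutoff > 0)
  ifelse(x < cutoff, "Benign", "Tumor")
}

#' Combined two-threshold rule
#'
#' @param x0 ratio threshold (default 0.06).
#' @param y0 CA19-9 threshold in U/ml (default 300).
#' @return list of class `combined_rule`.
#' @export
combined_rule <- function(x0 = 0.06, y0 = 300) {
  stopifnot(x0 > 0, y0 > 0)
  structure(list(x0 = x0, y0 = y0), class = "combined_rule")
}

#' Classify by the combined ratio + CA19-9 rule
#'
#' Benign only when the ratio is strictly below `x0` AND CA19-9 is strictly
#' below `y0`; everything else (including either boundary) is Tumor. A
#' missing CA19-9 degrades to the ratio-only rule with a logged warning.
#'
#' @param x ratio value(s).
#' @param y CA19-9 value(s) in U/ml; may contain NA.
#' @param rule a [combined_rule()].
#' @return character vector in {"Tumor", "Benign"}.
#' @export
classify_combined <- function(x, y, rule = combined_rule()) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  if (anyNA(y)) {
    warning("missing CA19-9 for ", sum(is.na(y)),
            " specimen(s): falling back to the ratio-only rule there")
  }
  ifelse(is.na(y), classify_ratio(x, rule$x0),
         ifelse(x < rule$x0 & y < rule$y0, "Benign", "Tumor"))
}

#' Confusion counts with sensitivity and specificity
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), reported as
#' percentages rounded half-up to 1 decimal.
#'
#' @param predicted predicted labels in {"Tumor", "Benign"} (or the truth
#'   alphabet).
#' @param truth true labels; `positive` defines the case class.
#' @param positive truth label counted as positive (default "PDAC").
#' @return list of class `confusion_result`: tp, fn, tn, fp, sensitivity,
#'   specificity (rounded half-up to 1 decimal) plus their `_raw`
#'   unrounded forms.
#' @export
confusion_metrics <- function(predicted, truth, positive = "PDAC") {
  stopifnot(length(predicted) == length(truth))
  pred_pos <- predicted %in% c("Tumor", positive)
  pred_neg <- predicted %in% c("Benign", setdiff(unique(truth), positive))
  if (any(!(pred_pos | pred_neg))) stop("unknown predicted label(s)")
  truth_pos <- truth == positive
  res <- list(tp = sum(pred_pos & truth_pos),
              fn = sum(!pred_pos & truth_pos),
              tn = sum(!pred_pos & !truth_pos),
              fp = sum(pred_pos & !truth_pos))
  res$sensitivity_raw <- 100 * res$tp / (res$tp + res$fn)
  res$specificity_raw <- 100 * res$tn / (res$tn + res$fp)
  res$sensitivity <- round_half_up(res$sensitivity_raw, 1)
  res$specificity <- round_half_up(res$specificity_raw, 1)
  structure(res, class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("TP %d  FN %d | TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' A fitted ratio biomarker
#'
#' Bundles a quotient marker with its cutoff, AUC and ROC points.
#'
#' @param numerator_id,denominator_id miRNA IDs.
#' @param cutoff positive decision cutoff.
#' @param auc AUC in [0, 1].
#' @param roc_points data.frame from [roc_curve()].
#' @return list of class `ratio_marker`.
#' @export
ratio_marker <- function(numerator_id, denominator_id, cutoff, auc,
                         roc_points = NULL) {
  stopifnot(cutoff > 0, auc >= 0, auc <= 1)
  structure(list(numerator_id = numerator_id,
                 denominator_id = denominator_id,
                 cutoff = cutoff, auc = auc, roc_points = roc_points),
            class = "ratio_marker")
}

#' Metastasis marker discovery within PDAC
#'
#' Applies the metastatic candidate filter (no fold-change clause) to the
#' M1-vs-M0 contrast among PDAC specimens, ranks candidates by AUC, keeps
#' those whose median expression split separates overall survival at
#' log-rank p < alpha, and searches ratio partners for the top retained
#' marker.
#'
#' @param counts raw counts restricted (or restrictable) to PDAC columns.
#' @param norm matching normalized matrix (`ev_norm` or matrix).
#' @param samples metadata with specimen_id, metastasis ("M0"/"M1"),
#'   os_days, os_event for the PDAC specimens.
#' @param thresholds a [filter_thresholds()]; the fold-change clause is not
#'   applied.
#' @param top_k number of ratio partners to report (default 5).
#' @param alpha_surv survival-filter significance level (default 0.05).
#' @return list: `candidates` (AUC-ranked table with log-rank p and a
#'   `survival_ok` flag), `numerator`, `partners` (ratio table with partner
#'   log-rank p), `best_pair` (a [ratio_marker()] or NULL).
#' @export
metastasis_candidates <- function(counts, norm, samples,
                                  thresholds = filter_thresholds(),
                                  top_k = 5, alpha_surv = 0.05) {
  x <- norm_values(norm)
  pdac <- samples$specimen_id[samples$diagnosis == "PDAC"]
  pdac <- intersect(colnames(x), pdac)
  x <- x[, pdac, drop = FALSE]
  counts <- counts[, pdac, drop = FALSE]
  meta <- samples[match(pdac, samples$specimen_id), ]
  if (length(unique(meta$metastasis)) < 2L)
    stop("need both M0 and M1 PDAC specimens")
  if (!any(meta$os_event %in% 1))
    stop("survival table has no events")

  de <- de_table(counts, x, meta$metastasis, "M1", "M0")
  cand <- candidate_filter(de, thresholds, mode = "metastatic")
  if (length(cand) == 0L)
    return(list(candidates = NULL, numerator = NULL, partners = NULL,
                best_pair = NULL))
  ranked <- rank_single_markers(x, meta$metastasis, cand, case = "M1")

  surv_p <- function(values) {
    grp <- ifelse(values >= stats::median(values), "high", "low")
    if (length(unique(grp)) < 2L) return(NA_real_)
    lr <- try(logrank_test(data.frame(specimen_id = pdac,
                                      os_days = meta$os_days,
                                      os_event = meta$os_event,
                                      group = grp)), silent = TRUE)
    if (inherits(lr, "try-error")) NA_real_ else lr$p_value
  }
  ranked$logrank_p <- vapply(ranked$mirna_id,
                             function(m) surv_p(x[m, ]), numeric(1))
  ranked$survival_ok <- !is.na(ranked$logrank_p) &
    ranked$logrank_p < alpha_surv
  retained <- ranked$mirna_id[ranked$survival_ok]
  if (length(retained) == 0L)
    return(list(candidates = ranked, numerator = NULL, partners = NULL,
                best_pair = NULL))

  numerator <- retained[1]
  partners <- ratio_search(x, meta$metastasis, numerator, cand, case = "M1")
  partners <- utils::head(partners, top_k)
  partners$logrank_p <- vapply(partners$denominator,
                               function(m) surv_p(x[m, ]), numeric(1))
  ok <- !is.na(partners$logrank_p) & partners$logrank_p < alpha_surv
  best_pair <- NULL
  if (any(ok)) {
    best <- partners[ok, ][1, ]
    den <- x[best$denominator, ] > 0
    ratio <- x[best$numerator, den] / x[best$denominator, den]
    best_pair <- ratio_marker(best$numerator, best$denominator,
                              cutoff = choose_cutoff(ratio,
                                                     meta$metastasis[den],
                                                     case = "M1"),
                              auc = best$auc,
                              roc_points = roc_curve(ratio,
                                                     meta$metastasis[den],
                                                     case = "M1"))
  }
  list(candidates = ranked, numerator = numerator, partners = partners,
       best_pair = best_pair)
}
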