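#' Kaplan-Meier product-limit estimate
#'
#' Wraps the standard product-limit estimator; specimens censored at an
#' event time are counted at risk at that time (events processed first).
#' The median is the earliest step time at which the survival estimate
#' drops to 0.5 or below, NA when never reached.
#'
#' @param records data.frame with columns os_days (>= 0) and os_event
#'   (1 = death observed, 0 = censored).
#' @return list of class `km_fit`: `time`, `surv`, `n_risk` (at each step
#'   time), `median_os`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L) stop("no survival records")
  stopifnot(all(records$os_days >= 0))
  fit <- survival::survfit(survival::Surv(os_days, os_event) ~ 1,
                           data = records)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]] else
    NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 median_os = med),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d step times, median OS %s\n",
              length(x$time),
              if (is.na(x$median_os)) "not reached" else
                sprintf("%.0f days", x$median_os)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each event time, observed minus hypergeometric-expected events in
#' the first group are accumulated and the variance-standardized sum is
#' referred to a chi-square distribution with 1 degree of freedom (no
#' continuity correction).
#'
#' @param records data.frame with columns os_days, os_event and group
#'   (exactly two levels, both nonempty, with at least one event overall).
#' @return list: `statistic` (chi-square), `p_value`, `n` per group.
#' @export
logrank_test <- function(records) {
  g <- unique(records$group)
  if (length(g) != 2L) stop("need exactly two groups")
  if (!any(records$os_event %in% 1)) stop("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(os_days, os_event) ~ group,
                           data = records, rho = 0)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = stats::setNames(as.vector(sd$n), sub("^group=", "", names(sd$n))))
}

#' Stratify specimens by a ratio cutoff
#'
#' "above" when the marker value exceeds the cutoff strictly; exact
#' equality falls to "below".
#'
#' @param values per-specimen ratio values.
#' @param cutoff positive cutoff (metastasis/prognosis default 0.15).
#' @return character vector in {"above", "below"}.
#' @export
stratify_by_ratio <- function(values, cutoff = 0.15) {
  stopifnot(cutoff > 0)
  ifelse(values > cutoff, "above", "below")
}
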