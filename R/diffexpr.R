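#' Log2 fold change of two group means
#'
#' Ratio-of-means reading with a pseudocount so the statistic stays finite
#' at zero means.
#'
#' @param mean_a,mean_b nonnegative group means (normalized expression).
#' @param pseudocount positive stabilizer added to both means (default 0.5).
#' @return `log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  stopifnot(all(mean_a >= 0), all(mean_b >= 0), pseudocount > 0)
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Per-miRNA two-group differential test
#'
#' `welch_log` is a two-sample unequal-variance (Welch) t-test on
#' `log2(normalized + 1)`. `moderated` uses the same log scale but squeezes
#' each miRNA's pooled variance toward a common prior estimated across
#' miRNAs by method of moments (empirical-Bayes shrinkage), gaining the
#' prior degrees of freedom. Both return two-sided p-values. miRNAs with no
#' variance in either group get statistic 0 and p = 1.
#'
#' @param norm an `ev_norm` or numeric matrix (miRNA x specimen).
#' @param labels group label per specimen (exactly two distinct values
#'   among specimens used).
#' @param method "welch_log" or "moderated".
#' @param group_a,group_b which label is which group; defaults to the two
#'   distinct labels in order of appearance (A first).
#' @return data.frame with mirna_id, statistic, df, p_value.
#' @export
de_test <- function(norm, labels, method = c("welch_log", "moderated"),
                    group_a = NULL, group_b = NULL) {
  method <- match.arg(method)
  x <- norm_values(norm)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) stop("labels must match specimen columns")
  lev <- unique(labels)
  if (is.null(group_a)) group_a <- lev[1]
  if (is.null(group_b)) group_b <- setdiff(lev, group_a)[1]
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 specimens")
  la <- log2(x[, ia, drop = FALSE] + 1)
  lb <- log2(x[, ib, drop = FALSE] + 1)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)

  if (method == "welch_log") {
    se2 <- va / na + vb / nb
    tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))),
                 na + nb - 2)
  } else {
    d <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / d
    # method-of-moments prior: Var(s^2) = s0^4 (2/d + 2/d0) across miRNAs
    m1 <- mean(s2); v1 <- stats::var(s2)
    ratio <- if (m1 > 0) v1 / m1^2 - 2 / d else 0
    d0 <- if (is.finite(ratio) && ratio > 1e-12) 2 / ratio else Inf
    s0_2 <- m1
    s2_tilde <- if (is.finite(d0)) (d0 * s0_2 + d * s2) / (d0 + d) else
      rep(s0_2, length(s2))
    se2 <- s2_tilde * (1 / na + 1 / nb)
    tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
    df <- rep(if (is.finite(d0)) d + d0 else 1e6, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(mirna_id = rownames(x), statistic = tt, df = df,
             p_value = pmin(pmax(p, .Machine$double.xmin), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: sort ascending, q_(i) = min over j >= i of
#' p_(j) * m / j, restore input order.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Candidate filter thresholds
#'
#' Defaults follow the discovery filter used for the diagnostic analysis:
#' expressed in all specimens, mean normalized expression >= 50 (inclusive),
#' |log2 fold change| > 1, p < 0.05.
#'
#' @param min_mean_norm mean-expression threshold (inclusive).
#' @param min_abs_log2fc fold-change threshold (strict); ignored in
#'   metastatic mode.
#' @param alpha significance threshold (strict).
#' @param use_fdr gate on BH-adjusted values instead of raw p.
#' @param mean_rule "either" (larger of the two group means, default) or
#'   "pooled" (mean of the two group means).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mean_norm = 50, min_abs_log2fc = 1,
                              alpha = 0.05, use_fdr = FALSE,
                              mean_rule = c("either", "pooled")) {
  stopifnot(min_mean_norm > 0, min_abs_log2fc >= 0, alpha > 0, alpha < 1)
  structure(list(min_mean_norm = min_mean_norm,
                 min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                 use_fdr = use_fdr, mean_rule = match.arg(mean_rule)),
            class = "filter_thresholds")
}

#' Differential-expression table for a two-group contrast
#'
#' Convenience wrapper combining group means of normalized expression,
#' log2 fold change, the differential test and BH adjustment.
#'
#' @param counts raw count matrix (for the expressed-in-all flag).
#' @param norm matching `ev_norm` (or normalized matrix).
#' @param labels per-specimen group labels.
#' @param group_a,group_b contrast groups (A vs B); specimens with other
#'   labels are ignored.
#' @param method test passed to [de_test()].
#' @param pseudocount passed to [log2_fold_change()].
#' @return data.frame: mirna_id, mean_a, mean_b, log2fc, p_value, fdr,
#'   expressed_in_all.
#' @export
de_table <- function(counts, norm, labels, group_a, group_b,
                     method = "welch_log", pseudocount = 0.5) {
  x <- norm_values(norm)
  keep <- labels %in% c(group_a, group_b)
  xs <- x[, keep, drop = FALSE]
  ls <- labels[keep]
  mean_a <- rowMeans(xs[, ls == group_a, drop = FALSE])
  mean_b <- rowMeans(xs[, ls == group_b, drop = FALSE])
  tst <- de_test(xs, ls, method = method, group_a = group_a,
                 group_b = group_b)
  data.frame(mirna_id = rownames(x),
             mean_a = mean_a, mean_b = mean_b,
             log2fc = log2_fold_change(mean_a, mean_b, pseudocount),
             p_value = tst$p_value, fdr = bh_fdr(tst$p_value),
             expressed_in_all = apply(counts[rownames(x), keep,
                                             drop = FALSE] >= 1, 1, all),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the candidate filter to a differential-expression table
#'
#' Diagnostic mode applies all four clauses (expressed in all specimens,
#' mean normalized expression >= threshold, |log2FC| > threshold,
#' p (or FDR) < alpha); metastatic mode omits the fold-change clause. The
#' mean clause uses the larger of the two group means by default.
#'
#' @param de table from [de_table()].
#' @param thresholds a [filter_thresholds()].
#' @param mode "diagnostic" or "metastatic".
#' @return character vector of passing miRNA IDs (input order); warns when
#'   empty.
#' @export
candidate_filter <- function(de, thresholds = filter_thresholds(),
                             mode = c("diagnostic", "metastatic")) {
  mode <- match.arg(mode)
  mean_stat <- switch(thresholds$mean_rule,
                      either = pmax(de$mean_a, de$mean_b),
                      pooled = (de$mean_a + de$mean_b) / 2)
  sig <- if (thresholds$use_fdr) de$fdr else de$p_value
  pass <- de$expressed_in_all &
    mean_stat >= thresholds$min_mean_norm &
    sig < thresholds$alpha
  if (mode == "diagnostic")
    pass <- pass & abs(de$log2fc) > thresholds$min_abs_log2fc
  out <- de$mirna_id[pass]
  if (length(out) == 0L)
    warning("candidate filter returned no miRNAs")
  out
}
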