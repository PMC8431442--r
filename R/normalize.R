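#' Select housekeeping miRNAs
#'
#' A miRNA is housekeeping when it has at least one read in every specimen;
#' these form the reference set for the per-specimen size factor.
#'
#' @param counts integer count matrix (miRNA x specimen).
#' @return character vector of housekeeping miRNA IDs, in input row order.
#' @export
select_housekeeping <- function(counts) {
  validate_counts(counts)
  hk <- rownames(counts)[apply(counts >= 1, 1, all)]
  if (length(hk) == 0L)
    stop("no housekeeping miRNA: no miRNA has >= 1 read in all specimens")
  hk
}

#' Per-specimen size factors
#'
#' The size factor of a specimen is the 75th percentile of its housekeeping
#' miRNA raw counts. The percentile convention is linear interpolation
#' (Hyndman-Fan type 7, the R default) by default; a nearest-rank
#' alternative (type 1) is available.
#'
#' @param counts integer count matrix.
#' @param housekeeping_ids nonempty subset of rownames(counts).
#' @param type quantile type, 7 (default) or 1.
#' @return named positive numeric vector, one factor per specimen.
#' @export
size_factor <- function(counts, housekeeping_ids = select_housekeeping(counts),
                        type = 7) {
  if (length(housekeeping_ids) == 0L) stop("housekeeping set is empty")
  if (!all(housekeeping_ids %in% rownames(counts)))
    stop("housekeeping IDs absent from the count matrix")
  sf <- apply(counts[housekeeping_ids, , drop = FALSE], 2, stats::quantile,
              probs = 0.75, type = type, names = FALSE)
  if (any(sf <= 0))
    stop("zero size factor for specimen(s): ",
         paste(colnames(counts)[sf <= 0], collapse = ", "))
  sf
}

#' Housekeeping-normalized expression
#'
#' Normalized expression = raw reads divided by the specimen's size factor
#' (75th percentile of its housekeeping counts).
#'
#' @param counts integer count matrix.
#' @param type quantile convention passed to [size_factor()].
#' @return list of class `ev_norm`: `values` (numeric matrix),
#'   `housekeeping_ids`, `size_factors`.
#' @export
normalize_counts <- function(counts, type = 7) {
  validate_counts(counts)
  hk <- select_housekeeping(counts)
  sf <- size_factor(counts, hk, type = type)
  values <- sweep(counts, 2, sf, "/")
  structure(list(values = values, housekeeping_ids = hk, size_factors = sf),
            class = "ev_norm")
}

#' @export
print.ev_norm <- function(x, ...) {
  cat(sprintf("Normalized miRNA matrix: %d miRNAs x %d specimens\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  housekeeping set: %d miRNAs; size factors %.3g - %.3g\n",
              length(x$housekeeping_ids), min(x$size_factors),
              max(x$size_factors)))
  invisible(x)
}

norm_values <- function(norm) {
  if (inherits(norm, "ev_norm")) norm$values else norm
}

#' Per-miRNA max scaling
#'
#' Divides each miRNA row by its maximum so highly expressed miRNAs do not
#' dominate the principal components. Rows whose maximum is 0 are dropped
#' (scaling undefined) with a message.
#'
#' @param norm an `ev_norm` or a numeric matrix.
#' @return numeric matrix in [0, 1], row maxima equal to 1.
#' @export
max_scale <- function(norm) {
  x <- norm_values(norm)
  mx <- apply(x, 1, max)
  drop <- mx == 0
  if (any(drop))
    stage_log("max_scale", "dropped %d all-zero miRNA row(s)", sum(drop))
  x <- x[!drop, , drop = FALSE]
  sweep(x, 1, mx[!drop], "/")
}

#' Principal components of specimens on max-scaled expression
#'
#' Specimens are observations and miRNAs variables. Variables are centered
#' (the standard convention; configurable) but not rescaled beyond the max
#' scaling already applied.
#'
#' @param scaled matrix from [max_scale()] (miRNA x specimen).
#' @param k number of components to keep.
#' @param center center variables before projection (default TRUE).
#' @return list with `coords` (specimen x PC matrix) and `var_frac`
#'   (fraction of variance per component, non-increasing).
#' @export
pca_specimens <- function(scaled, k = 2, center = TRUE) {
  x <- t(norm_values(scaled))    # specimens x miRNAs
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 specimens and >= 2 miRNAs")
  fit <- stats::prcomp(x, center = center, scale. = FALSE)
  if (all(fit$sdev == 0)) stop("rank-0 input: no variance across specimens")
  k <- min(k, ncol(fit$x))
  list(coords = fit$x[, seq_len(k), drop = FALSE],
       var_frac = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)])
}

#' Relative quantification by the 2^-ddCt method
#'
#' Standard qRT-PCR relative expression of a target gene versus a reference
#' gene, in a case specimen relative to a control specimen.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values.
#' @return relative expression `2^-ddCt`.
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
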