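#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from one global seed. Independent
#' draws (counts, clinical covariates, survival, replicate loops) use
#' sub-seeds derived deterministically from the global seed and a stream
#' name, so each stream can be reproduced in isolation without replaying
#' the others.
#'
#' @param seed integer global seed.
#' @param stream character stream label (e.g. "counts", "clinical").
#' @return an integer in [0, 2^31 - 1), usable with [set.seed()].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  # small string hash; kept below 2^31 so set.seed() accepts it everywhere
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# round half away from zero to `digits` decimals; base round() uses
# round-half-even which disagrees with clinically reported percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Validate a raw miRNA count matrix
#'
#' @param counts integer matrix, rows = miRNAs, columns = specimens, with
#'   unique dimnames.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (miRNA x specimen)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry miRNA rownames and specimen colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate miRNA IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate specimen IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (ncol(counts) < 2L) stop("need at least 2 specimens")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  invisible(counts)
}

# stage log line: one structured message per pipeline stage
stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
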