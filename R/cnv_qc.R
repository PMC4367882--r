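#' Log-R-ratio probe tracks
#'
#' Per-probe log-R ratios (LRR) from a two-channel CGH hybridization:
#' columns `chrom`, `pos`, `lrr`.  Positions must be strictly increasing
#' within each chromosome, and at least one chromosome needs two or more
#' probes so that consecutive-probe differences exist.
#'
#' @param probes Data frame with columns `chrom`, `pos`, `lrr`.
#' @return A data frame of class `lrr_track`, sorted by chromosome and
#'   position.
#' @export
lrr_track <- function(probes) {
  p <- as.data.frame(probes, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "lrr") %in% names(p)))
  p$chrom <- norm_chrom(p$chrom)
  p <- p[order(p$chrom, p$pos), ]
  dup <- unlist(lapply(split(p$pos, p$chrom), function(x) c(FALSE, diff(x) <= 0)))
  if (any(dup))
    stop("probe positions must be strictly increasing within a chromosome")
  if (!any(table(p$chrom) >= 2))
    stop("need at least 2 probes on some chromosome")
  rownames(p) <- NULL
  class(p) <- c("lrr_track", "data.frame")
  p
}

## consecutive-probe LRR differences, never crossing a chromosome boundary
lrr_diffs <- function(track) {
  unlist(lapply(split(track$lrr, track$chrom), function(x) {
    if (length(x) < 2) numeric(0) else diff(x)
  }), use.names = FALSE)
}

#' mad1.dr hybridization-noise score
#'
#' The median absolute deviation (unscaled) of the LRR difference between
#' consecutive probes along each chromosome, pooled genome-wide.  For
#' i.i.d. Gaussian probe noise with standard deviation sigma the expected
#' score is `0.6745 * sigma * sqrt(2)`, since consecutive differences are
#' Gaussian with variance `2 sigma^2`.  Hybridizations scoring above 0.23
#' are conventionally considered too noisy to call.
#'
#' @param track An [lrr_track()].
#' @return The mad1.dr score (unitless, >= 0).
#' @export
qc_mad1dr <- function(track) {
  d <- lrr_diffs(track)
  if (length(d) == 0) stop("no consecutive-probe pairs in track")
  stats::median(abs(d - stats::median(d)))
}

#' Robust variance hybridization-noise score
#'
#' Mean of the squared consecutive-probe LRR differences after trimming
#' the top and bottom `trim_fraction` of the ordered values.  The trim
#' absorbs the variance spikes expected at true CNV breakpoints, so the
#' score reflects probe noise rather than copy-number signal.  Scores
#' below roughly 0.15-0.2 are conventionally acceptable.
#'
#' @param track An [lrr_track()].
#' @param trim_fraction Fraction trimmed from each tail (default 0.03).
#' @return The robust variance score (unitless, >= 0).
#' @export
qc_robust_variance <- function(track, trim_fraction = 0.03) {
  d <- lrr_diffs(track)
  if (length(d) == 0) stop("no consecutive-probe pairs in track")
  v <- sort(d^2)
  k <- floor(trim_fraction * length(v))
  if (2 * k >= length(v)) stop("trim_fraction removes all values")
  mean(v[(k + 1):(length(v) - k)])
}

#' Combined sample QC decision
#'
#' @param track An [lrr_track()].
#' @param mad1dr_cutoff Maximum acceptable mad1.dr score (default 0.23).
#' @param robust_variance_cutoff Maximum acceptable robust variance score
#'   (default 0.2, the permissive end of the conventional 0.15-0.2 range).
#' @param trim_fraction Trim for the robust variance score.
#' @return A list of class `qc_scores` with `mad1_dr`, `robust_variance`
#'   and `pass`.
#' @export
qc_scores <- function(track, mad1dr_cutoff = 0.23,
                      robust_variance_cutoff = 0.2, trim_fraction = 0.03) {
  m <- qc_mad1dr(track)
  rv <- qc_robust_variance(track, trim_fraction)
  structure(list(mad1_dr = m, robust_variance = rv,
                 pass = m <= mad1dr_cutoff & rv <= robust_variance_cutoff),
            class = "qc_scores")
}

#' @export
print.qc_scores <- function(x, ...) {
  cat(sprintf("<qc_scores> mad1.dr = %.4f, robust variance = %.4f, %s\n",
              x$mad1_dr, x$robust_variance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
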