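#' Consecutive-significance threshold length
#'
#' Converts a threshold fraction of the low-pass window (the reciprocal of
#' the low-pass cutoff) into a minimum run length in samples:
#' `ceiling(fraction * fs / lowpass_hz)`. Fraction 0 means no thresholding
#' and resolves to 1 sample (every flagged point is kept). At 10 Hz sampling
#' with a 2 Hz cutoff the window is 0.5 s, so the half-window threshold is 3
#' samples (rounded up) and the full-window threshold is 5 samples.
#'
#' @param fs Sampling rate, Hz.
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param fraction Fraction of the low-pass window (commonly 0, 0.5, or 1).
#' @return Minimum run length in samples (integer >= 1).
#' @examples
#' threshold_length(10, 2, 1)    # 5
#' threshold_length(10, 2, 0.5)  # 3
#' @export
threshold_length <- function(fs, lowpass_hz, fraction) {
  stopifnot(fs > 0, lowpass_hz > 0, fraction >= 0)
  if (fraction == 0) return(1L)
  as.integer(ceiling(fraction * fs / lowpass_hz))
}

#' Enforce a minimum run of consecutive significant samples
#'
#' Flags are retained only where they belong to a maximal run of consecutive
#' significant timepoints of length at least `k`; shorter runs are zeroed.
#' Runs are defined on the raw significance flags regardless of effect
#' direction, so a run that switches from significantly-above to
#' significantly-below the null without a gap counts as one run; pass a
#' `direction` vector to split runs at direction changes instead. Runs
#' touching the window edge count with their in-window length.
#'
#' @param mask A [significance_mask()] or a logical vector.
#' @param k Minimum run length in samples (>= 1); `k = 1` is the identity.
#' @param direction Optional numeric/sign vector (same length as the mask)
#'   used to split runs where the sign changes.
#' @return The thresholded mask, same type as the input (`consec_threshold`
#'   set to `k` for a `significance_mask`).
#' @examples
#' apply_consecutive_threshold(c(TRUE, TRUE, FALSE, rep(TRUE, 5)), k = 5)
#' @export
apply_consecutive_threshold <- function(mask, k, direction = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a single sample count >= 1")
  k <- as.integer(k)
  flags <- mask_flags_(mask)
  if (is.null(direction)) {
    r <- rle(flags)
    r$values <- r$values & r$lengths >= k
    out <- inverse.rle(r)
  } else {
    if (length(direction) != length(flags))
      stop("'direction' must match the mask length")
    grp <- cumsum(c(TRUE, diff(as.integer(flags)) != 0 |
                      (sign(direction)[-1L] != sign(direction)[-length(direction)])))
    keep <- stats::ave(flags, grp, FUN = function(f) f & length(f) >= k) > 0
    out <- as.logical(keep)
  }
  if (inherits(mask, "significance_mask"))
    significance_mask(out, alpha = mask$alpha, consec_threshold = k)
  else out
}
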