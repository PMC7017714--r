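#' Per-timepoint significance mask
#'
#' The common currency of all detectors: a logical flag per timepoint plus
#' the per-comparison alpha and the consecutive-run threshold (in samples)
#' that has been applied (0 = none).
#'
#' @param flags Logical vector, one flag per timepoint.
#' @param alpha Per-comparison Type I rate associated with the flags.
#' @param consec_threshold Minimum run length already enforced (samples).
#' @return A `significance_mask` object.
#' @export
significance_mask <- function(flags, alpha, consec_threshold = 0L) {
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("'flags' must not contain NA")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  structure(list(flags = flags, alpha = alpha,
                 consec_threshold = as.integer(consec_threshold)),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "significance_mask: %d/%d timepoints flagged (alpha = %g, consec >= %d)\n",
    sum(x$flags), length(x$flags), x$alpha, x$consec_threshold))
  invisible(x)
}

mask_flags_ <- function(mask) {
  if (inherits(mask, "significance_mask")) mask$flags else as.logical(mask)
}
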