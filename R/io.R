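#' Write a trace matrix to CSV
#'
#' The first column holds the subject/trial id; the remaining column names
#' carry the timepoints in seconds (first sample at `t_offset`).
#'
#' @param x A [trace_matrix()].
#' @param path Output CSV path.
#' @param t_offset Time of the first sample, seconds.
#' @return `path`, invisibly.
#' @export
write_trace_matrix <- function(x, path, t_offset = 0) {
  fs <- sampling_rate(x)
  tt <- (seq_len(ncol(x)) - 1L) / fs + t_offset
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  # %.17g keeps the values bit-identical across a write/read round trip
  chr <- matrix(sprintf("%.17g", unclass(x)), nrow(x), ncol(x))
  df <- data.frame(subject = ids, chr, check.names = FALSE)
  colnames(df) <- c("subject", format(tt, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace matrix from CSV
#'
#' Expects the layout written by [write_trace_matrix()]: a header row of
#' timepoints in seconds (uniformly spaced; the sampling rate is inferred
#' from the grid), a first column of subject ids, and one numeric row per
#' trace.
#'
#' @param path CSV path.
#' @return A [trace_matrix()] with subject ids as row names.
#' @export
read_trace_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a subject column plus timepoint columns")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- which(rowSums(!is.finite(vals)) > 0L)
  if (length(bad))
    stop("non-numeric or missing values in row(s): ",
         paste(ids[bad], collapse = ", "))
  tt <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(tt)) stop("header row must carry timepoints in seconds")
  dt <- diff(tt)
  if (length(dt) < 1L) stop("need at least 2 timepoints")
  if (any(abs(dt - dt[1L]) > 1e-6 * abs(dt[1L])))
    stop("time grid is not uniform; cannot infer a sampling rate")
  out <- trace_matrix(vals, fs = 1 / dt[1L])
  rownames(out) <- ids
  out
}

#' Significant runs in a mask
#'
#' Converts a significance mask into a table of maximal significant runs
#' with half-open time intervals `[start_s, end_s)`.
#'
#' @param mask A [significance_mask()] or logical vector.
#' @param fs Sampling rate, Hz.
#' @param center Optional center waveform used to report each run's
#'   direction and peak value.
#' @param t_offset Time of the first sample, seconds.
#' @return Data frame with columns `start_index`, `end_index` (1-based,
#'   inclusive), `start_s`, `end_s`, `direction`, `peak_center`.
#' @export
significant_runs <- function(mask, fs, center = NULL, t_offset = 0) {
  flags <- mask_flags_(mask)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_index = starts[keep], end_index = ends[keep])
  out$start_s <- (out$start_index - 1L) / fs + t_offset
  out$end_s <- out$end_index / fs + t_offset
  if (is.null(center) || nrow(out) == 0L) {
    out$direction <- rep(NA_character_, nrow(out))
    out$peak_center <- rep(NA_real_, nrow(out))
  } else {
    pk <- vapply(seq_len(nrow(out)), function(i) {
      seg <- center[out$start_index[i]:out$end_index[i]]
      seg[which.max(abs(seg))]
    }, numeric(1L))
    out$direction <- ifelse(pk >= 0, "up", "down")
    out$peak_center <- pk
  }
  out
}

#' Write a per-timepoint analysis report
#'
#' Emits a per-timepoint CSV (center, bounds, p-values, raw and thresholded
#' flags) plus a JSON summary listing the significant runs of the
#' thresholded mask.
#'
#' @param path_csv,path_json Output paths.
#' @param fs Sampling rate, Hz.
#' @param mask_raw,mask_thresholded [significance_mask()] objects (or
#'   logical vectors) before and after consecutive thresholding.
#' @param center Center waveform (mean or mean difference).
#' @param lower,upper Optional CI bounds.
#' @param p Optional permutation p-values.
#' @param t_offset Time of the first sample, seconds.
#' @return Invisibly, the runs data frame written to the JSON summary.
#' @export
write_analysis_report <- function(path_csv, path_json, fs, mask_raw,
                                  mask_thresholded, center, lower = NULL,
                                  upper = NULL, p = NULL, t_offset = 0) {
  fr <- mask_flags_(mask_raw)
  ft <- mask_flags_(mask_thresholded)
  nt <- length(center)
  if (length(fr) != nt || length(ft) != nt)
    stop("masks and center waveform must have equal lengths")
  df <- data.frame(
    time = (seq_len(nt) - 1L) / fs + t_offset,
    center = center,
    lower = if (is.null(lower)) NA_real_ else lower,
    upper = if (is.null(upper)) NA_real_ else upper,
    p = if (is.null(p)) NA_real_ else p,
    flag_raw = as.integer(fr),
    flag_thresholded = as.integer(ft))
  utils::write.csv(df, path_csv, row.names = FALSE, quote = FALSE)
  runs <- significant_runs(ft, fs = fs, center = center, t_offset = t_offset)
  k <- if (inherits(mask_thresholded, "significance_mask"))
    mask_thresholded$consec_threshold else NA_integer_
  jsonlite::write_json(
    list(fs = fs, t_offset = t_offset, consec_threshold = k,
         n_timepoints = nt, runs = runs),
    path_json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(runs)
}

#' Read a Monte Carlo study configuration from YAML
#'
#' The YAML mirrors [study_config()]; a `generator` block mirrors
#' [generator_params()].
#'
#' @param path YAML path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(generator_params, y$generator)
  do.call(study_config, y)
}
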