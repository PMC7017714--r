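#' Parameters of the synthetic peri-event signal generator
#'
#' The generator emulates subject-averaged fiber photometry dF traces: each
#' underlying "line" is a zero-baseline peri-event window of low-pass filtered
#' white Gaussian noise, optionally carrying a 1-s additive parabolic
#' transient whose magnitude is half-normal (`|z|`, z standard normal). ERT
#' lines carry the transient at the halfway point of the window; null lines
#' carry, with probability `null_transient_prob`, an unrelated transient at a
#' uniform-random position (and random sign, see below). Subjects are means of
#' a uniform-random number of lines.
#'
#' `noise_power` is the variance of the white noise before filtering; the
#' default 0.1 follows the convention of adding noise at a stated SNR (10 dB)
#' against a 0 dBW reference, the natural reading when the baseline is
#' identically zero. The noise is filtered with a zero-phase (forward-backward)
#' 2nd-order Butterworth low-pass at `lowpass_hz`; the transient is added
#' after filtering.
#'
#' Null-condition transients are signed (+/- with equal probability) by
#' default so that the null population has zero pointwise mean; unrelated
#' transients in real recordings are excitatory or inhibitory alike. Set
#' `signed_null_transients = FALSE` for positive-only unrelated transients
#' (this biases the null mean upward by roughly
#' `prob * E|z| * mean(parabola) * duration/window`).
#'
#' @param n_points Timepoints per trace (default 100, i.e. 10 s at 10 Hz).
#' @param fs Sampling rate, Hz.
#' @param noise_power Variance of the pre-filter white Gaussian noise (dF^2).
#' @param lowpass_hz Low-pass cutoff, Hz; must be below the Nyquist rate.
#' @param transient_duration Transient duration, seconds.
#' @param magnitude_scale Scale factor applied to the half-normal magnitude.
#' @param null_transient_prob Probability that a null-condition line carries
#'   an unrelated transient.
#' @param signed_null_transients Logical; give null-condition transients a
#'   random sign (default `TRUE`).
#' @param lines_per_subject_range Integer interval `c(lo, hi)` from which the
#'   number of lines averaged into one subject is drawn uniformly.
#' @param population_lines Lines per condition in a generated population.
#' @param population_subjects Subjects per condition in a generated population.
#' @param seed Optional integer seed making population generation
#'   reproducible.
#' @return A `generator_params` list.
#' @seealso [generate_populations()], [generate_line()]
#' @export
generator_params <- function(n_points = 100L, fs = 10, noise_power = 0.1,
                             lowpass_hz = 2, transient_duration = 1,
                             magnitude_scale = 1, null_transient_prob = 0.5,
                             signed_null_transients = TRUE,
                             lines_per_subject_range = c(1L, 31L),
                             population_lines = 10000L,
                             population_subjects = 1000L,
                             seed = NULL) {
  p <- list(n_points = as.integer(n_points), fs = fs, noise_power = noise_power,
            lowpass_hz = lowpass_hz, transient_duration = transient_duration,
            magnitude_scale = magnitude_scale,
            null_transient_prob = null_transient_prob,
            signed_null_transients = isTRUE(signed_null_transients),
            lines_per_subject_range = as.integer(lines_per_subject_range),
            population_lines = as.integer(population_lines),
            population_subjects = as.integer(population_subjects),
            seed = seed)
  stopifnot(p$n_points >= 1L, p$fs > 0, p$noise_power >= 0)
  if (!(p$lowpass_hz > 0 && p$lowpass_hz < p$fs / 2))
    stop("'lowpass_hz' must lie in (0, fs/2)")
  if (p$transient_duration * p$fs < 2)
    stop("'transient_duration' must span at least 2 samples")
  if (p$null_transient_prob < 0 || p$null_transient_prob > 1)
    stop("'null_transient_prob' must be a probability")
  r <- p$lines_per_subject_range
  if (length(r) != 2L || any(r < 1L) || r[1L] > r[2L])
    stop("'lines_per_subject_range' must be a positive ordered pair")
  tk <- transient_samples_(p)
  if (tk > p$n_points)
    stop("transient does not fit inside the peri-event window")
  stopifnot(p$population_lines >= 1L, p$population_subjects >= 1L)
  class(p) <- "generator_params"
  p
}

transient_samples_ <- function(params) as.integer(round(params$transient_duration * params$fs))

#' Timepoint indices of the ERT transient support
#'
#' 1-based column indices of the transient inserted at the halfway point of
#' the window in the ERT condition (samples 51-60 at the defaults).
#'
#' @param params A [generator_params()] object.
#' @return Integer vector of column indices.
#' @export
transient_support <- function(params) {
  k <- transient_samples_(params)
  start <- params$n_points %/% 2L + 1L
  seq.int(start, start + k - 1L)
}

#' Draw half-normal transient magnitudes
#'
#' Magnitudes are the positive tail of the z distribution: `scale * |z|` with
#' z standard normal, so the mean magnitude is `scale * sqrt(2/pi)` (~0.798
#' at scale 1).
#'
#' @param n Number of draws.
#' @param scale Scale factor.
#' @return Numeric vector of non-negative magnitudes.
#' @export
sample_transient_magnitude <- function(n = 1L, scale = 1) {
  scale * abs(stats::rnorm(n))
}

#' Sampled parabolic transient
#'
#' A transient is a one-`duration` parabola sampled on a symmetric grid of
#' `round(duration * fs)` points (half-sample offsets from the window edges),
#' rescaled so its sampled peak equals `magnitude`. The endpoints are the
#' near-zero edge values of the parabola.
#'
#' @param duration Transient duration, seconds (positive).
#' @param fs Sampling rate, Hz.
#' @param magnitude Peak dF (may be negative for an inhibitory transient).
#' @return Numeric vector of `round(duration * fs)` samples.
#' @examples
#' parabolic_transient(1, 10, 1)
#' @export
parabolic_transient <- function(duration, fs, magnitude) {
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be positive")
  k <- as.integer(round(duration * fs))
  if (k < 2L) stop("transient must span at least 2 samples")
  tt <- (seq_len(k) - 0.5) / k
  y <- 1 - (2 * tt - 1)^2
  magnitude * y / max(y)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero group delay) 2nd-order Butterworth low-pass, the
#' filter used to shape the generator's noise. Accepts a vector or a matrix
#' of traces (rows = traces).
#'
#' @param x Numeric vector, or matrix with one trace per row.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (0 < cutoff < fs/2).
#' @return Filtered data with the shape of `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff) {
  if (!(cutoff > 0 && cutoff < fs / 2)) stop("'cutoff' must lie in (0, fs/2)")
  bf <- signal::butter(2, cutoff / (fs / 2))
  if (is.matrix(x)) t(apply(x, 1L, function(v) signal::filtfilt(bf, v)))
  else signal::filtfilt(bf, x)
}

# n filtered noise lines as an n x n_points matrix (rows = lines).
noise_lines_ <- function(n, params) {
  if (params$noise_power == 0)
    return(matrix(0, n, params$n_points))
  white <- matrix(stats::rnorm(n * params$n_points, sd = sqrt(params$noise_power)),
                  params$n_points, n)
  bf <- signal::butter(2, params$lowpass_hz / (params$fs / 2))
  t(apply(white, 2L, function(v) signal::filtfilt(bf, v)))
}

#' Generate one noise-only line
#'
#' A zero-baseline peri-event trace of low-pass filtered white Gaussian
#' noise; no transient.
#'
#' @param params A [generator_params()] object.
#' @return Numeric vector of length `n_points` with an `fs` attribute.
#' @export
generate_noise_line <- function(params) {
  structure(drop(noise_lines_(1L, params)), fs = params$fs)
}

# Add one transient in place; start0 is the 0-based start index.
add_transient_ <- function(values, start0, magnitude, params) {
  k <- transient_samples_(params)
  idx <- seq.int(start0 + 1L, start0 + k)
  values[idx] <- values[idx] + parabolic_transient(params$transient_duration,
                                                   params$fs, magnitude)
  values
}

#' Generate one artificial line
#'
#' ERT lines carry a half-normal-magnitude parabolic transient starting at
#' the halfway point of the window. Null lines carry, with probability
#' `null_transient_prob`, an unrelated transient at a uniform-random start
#' position (fitting wholly inside the window) with a random sign if
#' `signed_null_transients` is set; otherwise they are pure noise.
#'
#' @param condition `"null"` or `"ert"`.
#' @param params A [generator_params()] object.
#' @param magnitude Optional fixed transient magnitude overriding the
#'   half-normal draw (used mainly for noise-free checks).
#' @return Numeric vector of length `n_points` with an `fs` attribute.
#' @export
generate_line <- function(condition = c("null", "ert"), params, magnitude = NULL) {
  condition <- match.arg(condition)
  v <- drop(noise_lines_(1L, params))
  k <- transient_samples_(params)
  if (condition == "ert") {
    m <- if (is.null(magnitude)) sample_transient_magnitude(1L, params$magnitude_scale) else magnitude
    v <- add_transient_(v, params$n_points %/% 2L, m, params)
  } else if (stats::runif(1L) < params$null_transient_prob) {
    start0 <- sample.int(params$n_points - k + 1L, 1L) - 1L
    m <- if (is.null(magnitude)) sample_transient_magnitude(1L, params$magnitude_scale) else magnitude
    if (params$signed_null_transients) m <- m * sample(c(-1, 1), 1L)
    v <- add_transient_(v, start0, m, params)
  }
  structure(v, fs = params$fs)
}

#' Generate one subject trace
#'
#' A subject is the arithmetic mean of `k` freshly generated lines, with `k`
#' drawn uniformly from `lines_per_subject_range`.
#'
#' @inheritParams generate_line
#' @return Numeric vector of length `n_points` with attributes `fs` and
#'   `n_lines` (the number of lines averaged).
#' @export
generate_subject <- function(condition = c("null", "ert"), params) {
  condition <- match.arg(condition)
  r <- params$lines_per_subject_range
  k <- if (r[1L] == r[2L]) r[1L] else sample(seq.int(r[1L], r[2L]), 1L)
  lines <- t(vapply(seq_len(k),
                    function(i) as.numeric(generate_line(condition, params)),
                    numeric(params$n_points)))
  structure(colMeans(lines), fs = params$fs, n_lines = k)
}

# Lines matrix for one condition (rows = lines).
condition_lines_ <- function(condition, n, params) {
  X <- noise_lines_(n, params)
  k <- transient_samples_(params)
  if (condition == "ert") {
    mags <- sample_transient_magnitude(n, params$magnitude_scale)
    half0 <- params$n_points %/% 2L
    for (i in seq_len(n)) X[i, ] <- add_transient_(X[i, ], half0, mags[i], params)
  } else {
    has <- stats::runif(n) < params$null_transient_prob
    for (i in which(has)) {
      m <- sample_transient_magnitude(1L, params$magnitude_scale)
      if (params$signed_null_transients) m <- m * sample(c(-1, 1), 1L)
      start0 <- sample.int(params$n_points - k + 1L, 1L) - 1L
      X[i, ] <- add_transient_(X[i, ], start0, m, params)
    }
  }
  X
}

#' Generate the null- and ERT-condition subject populations
#'
#' For each condition, `population_lines` lines are generated, and
#' `population_subjects` subjects are formed by sampling (without
#' replacement) and averaging a uniform-random number of lines from that
#' condition's line pool. Fully reproducible when `params$seed` is set.
#'
#' @param params A [generator_params()] object.
#' @return A list with `trace_matrix` elements `null` and `ert`.
#' @examples
#' gp <- generator_params(population_lines = 200, population_subjects = 40,
#'                        seed = 1)
#' pops <- generate_populations(gp)
#' pops$ert
#' @export
generate_populations <- function(params) {
  with_seed_(params$seed, {
    out <- lapply(c(null = "null", ert = "ert"), function(cond) {
      lines <- condition_lines_(cond, params$population_lines, params)
      r <- params$lines_per_subject_range
      ks <- if (r[1L] == r[2L]) rep(r[1L], params$population_subjects)
            else sample(seq.int(r[1L], r[2L]), params$population_subjects, replace = TRUE)
      subj <- t(vapply(ks, function(k) {
        rows <- sample.int(params$population_lines, k)
        colMeans(lines[rows, , drop = FALSE])
      }, numeric(params$n_points)))
      trace_matrix(subj, fs = params$fs, condition = cond)
    })
    out
  })
}
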