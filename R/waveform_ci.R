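#' @title Pointwise waveform confidence intervals
#' @description A `waveform_ci` holds pointwise lower/upper bounds around a
#'   center waveform (a sample mean or mean difference) at a stated
#'   confidence level. Periods where the interval excludes the null value
#'   flag candidate event-related transients; see [significance_from_ci()].
#' @name waveform_ci
NULL

new_waveform_ci <- function(lower, upper, center, level, method, n) {
  stopifnot(length(lower) == length(upper), length(center) == length(lower),
            all(lower <= upper + 1e-12))
  structure(list(lower = lower, upper = upper, center = center,
                 level = level, method = method, n = n),
            class = "waveform_ci")
}

#' @export
print.waveform_ci <- function(x, ...) {
  cat(sprintf("waveform_ci (%s): %d timepoints, %g%% level, n = %s\n",
              x$method, length(x$center), 100 * x$level,
              paste(x$n, collapse = " vs ")))
  invisible(x)
}

check_level_ <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
}

col_sds_ <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(colSums((x - rep(m, each = n))^2) / (n - 1L))
}

#' Parametric t interval across the waveform
#'
#' For every timepoint, `mean +/- SEM * t_crit` with `df = n - 1` and a
#' two-sided critical value.
#'
#' @param data A [trace_matrix()] (or matrix), rows = subjects/trials.
#' @param level Confidence level in (0, 1).
#' @return A [waveform_ci] object.
#' @examples
#' t_interval(trace_matrix(matrix(rnorm(30), 6, 5), fs = 10))
#' @export
t_interval <- function(data, level = 0.95) {
  check_level_(level)
  x <- as_matrix_(data)
  n <- nrow(x)
  if (n < 2L) stop("t interval needs at least 2 traces (SEM undefined)")
  m <- colMeans(x)
  sem <- col_sds_(x) / sqrt(n)
  crit <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  new_waveform_ci(m - crit * sem, m + crit * sem, m, level, "t", n)
}

# n_boot x n index draws mapped to a (n_boot x nrow) row-weight matrix so all
# bootstrap means come from one matrix product.
boot_weights_ <- function(n, n_boot) {
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  W <- matrix(0, n_boot, n)
  for (j in seq_len(n)) {
    ij <- cbind(seq_len(n_boot), idx[, j])
    W[ij] <- W[ij] + 1
  }
  W / n
}

col_quantiles_ <- function(x, probs) {
  apply(x, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
}

#' Expanded percentile bootstrap interval across the waveform
#'
#' Whole traces (rows) are resampled with replacement `n_boot` times; the
#' bounds at each timepoint are percentiles of the bootstrap means (2.5/97.5
#' at 95%, 0.5/99.5 at 99%), computed with linear interpolation between order
#' statistics. With `expand = TRUE` (the default) each bound is moved away
#' from the sample mean by the factor `n/(n-1)`, countering the percentile
#' interval's small-sample narrowness bias.
#'
#' @inheritParams t_interval
#' @param n_boot Number of bootstrap resamples (1000 or more recommended).
#' @param expand Apply the `n/(n-1)` expansion.
#' @param seed Optional seed for the resampling.
#' @return A [waveform_ci] object.
#' @export
bootstrap_interval <- function(data, level = 0.95, n_boot = 1000L,
                               expand = TRUE, seed = NULL) {
  check_level_(level)
  x <- as_matrix_(data)
  n <- nrow(x)
  if (n_boot < 1L) stop("'n_boot' must be at least 1")
  if (expand && n < 2L)
    stop("expansion factor n/(n-1) is undefined at n = 1")
  if (n < 1L) stop("need at least one trace")
  a <- (1 - level) / 2
  q <- with_seed_(seed, {
    B <- boot_weights_(n, n_boot) %*% x
    col_quantiles_(B, c(a, 1 - a))
  })
  m <- colMeans(x)
  lower <- q[1L, ]; upper <- q[2L, ]
  if (expand) {
    f <- n / (n - 1L)
    lower <- m + (lower - m) * f
    upper <- m + (upper - m) * f
  }
  new_waveform_ci(lower, upper, m, level, "bootstrap", n)
}

welch_interval_ <- function(ma, mb, va, vb, na, nb, level) {
  se2 <- va / na + vb / nb
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L)),
               1)
  hw <- ifelse(se2 > 0, stats::qt(1 - (1 - level) / 2, df) * sqrt(se2), 0)
  list(lower = (ma - mb) - hw, upper = (ma - mb) + hw)
}

#' Two-sample t interval on the mean-difference waveform
#'
#' Pointwise confidence interval on `mean(a) - mean(b)` with Welch (unequal
#' variance) degrees of freedom.
#'
#' @param a,b [trace_matrix()] objects with equal trace lengths.
#' @param level Confidence level in (0, 1).
#' @return A [waveform_ci] object (`n` holds both sample sizes).
#' @export
two_sample_t_interval <- function(a, b, level = 0.95) {
  check_level_(level)
  xa <- as_matrix_(a); xb <- as_matrix_(b)
  if (ncol(xa) != ncol(xb)) stop("'a' and 'b' must have equal trace lengths")
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2L || nb < 2L) stop("both samples need at least 2 traces")
  ma <- colMeans(xa); mb <- colMeans(xb)
  w <- welch_interval_(ma, mb, col_sds_(xa)^2, col_sds_(xb)^2, na, nb, level)
  new_waveform_ci(w$lower, w$upper, ma - mb, level, "t", c(na, nb))
}

#' Two-sample bootstrap interval on the mean-difference waveform
#'
#' Per replicate, both samples are resampled independently with replacement
#' and `mean(a*) - mean(b*)` recorded; bounds are pointwise percentiles of
#' that bootstrap difference distribution.
#'
#' @inheritParams two_sample_t_interval
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional seed for the resampling.
#' @return A [waveform_ci] object.
#' @export
two_sample_bootstrap_interval <- function(a, b, level = 0.95, n_boot = 1000L,
                                          seed = NULL) {
  check_level_(level)
  xa <- as_matrix_(a); xb <- as_matrix_(b)
  if (ncol(xa) != ncol(xb)) stop("'a' and 'b' must have equal trace lengths")
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2L || nb < 2L) stop("both samples need at least 2 traces")
  alpha2 <- (1 - level) / 2
  q <- with_seed_(seed, {
    D <- boot_weights_(na, n_boot) %*% xa - boot_weights_(nb, n_boot) %*% xb
    col_quantiles_(D, c(alpha2, 1 - alpha2))
  })
  new_waveform_ci(q[1L, ], q[2L, ], colMeans(xa) - colMeans(xb), level,
                  "bootstrap", c(na, nb))
}

#' Significance mask from a waveform confidence interval
#'
#' A timepoint is flagged significant when the (closed) interval does not
#' contain the null value: an interval merely touching the null is counted
#' as containing it (conservative tie-break).
#'
#' @param ci A [waveform_ci] object.
#' @param null_value The null dF value (default 0).
#' @return A [significance_mask()] with `alpha = 1 - level`.
#' @export
significance_from_ci <- function(ci, null_value = 0) {
  stopifnot(inherits(ci, "waveform_ci"))
  flags <- null_value < ci$lower | null_value > ci$upper
  significance_mask(flags, alpha = 1 - ci$level)
}

#' Windowed summary statistics per trace
#'
#' Convenience summary-statistic extraction for comparison with classical
#' AUC/peak analyses: trapezoidal area under the curve and maximum dF per
#' trace over a time window.
#'
#' @param data A [trace_matrix()].
#' @param window `c(from, to)` in seconds, relative to the first sample at
#'   t = 0.
#' @return A data frame with one row per trace and columns `auc` (dF*s) and
#'   `peak` (dF).
#' @export
summarize_window <- function(data, window) {
  x <- as_matrix_(data)
  fs <- if (inherits(data, "trace_matrix")) sampling_rate(data) else
    stop("'data' must be a trace_matrix (sampling rate needed)")
  tt <- (seq_len(ncol(x)) - 1L) / fs
  sel <- which(tt >= window[1L] & tt <= window[2L])
  if (length(sel) < 2L) stop("window selects fewer than 2 timepoints")
  y <- x[, sel, drop = FALSE]
  auc <- (rowSums(y) - (y[, 1L] + y[, ncol(y)]) / 2) / fs
  data.frame(auc = auc, peak = apply(y, 1L, max))
}
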