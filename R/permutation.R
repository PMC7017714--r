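#' Pointwise two-sample permutation test across the waveform
#'
#' Traces are reassigned between the two groups as whole rows, and at every
#' timepoint the p-value is the proportion of reassignments whose mean
#' difference is at least as extreme as the observed one. When the number of
#' distinct assignments `C(n_a + n_b, n_a)` does not exceed `max_perm`, all
#' of them are enumerated (the observed assignment included), making the
#' p-values exact; otherwise `max_perm` random reassignments are drawn and
#' the observed statistic is added to the permutation set
#' (`p = (b + 1) / (m + 1)`), preserving validity. Either way p is never 0.
#'
#' `tail = "two"` (default) compares absolute mean differences; ties count as
#' extreme. `tail = "one"` counts reassignments with `mean(a*) - mean(b*)`
#' at least the observed difference.
#'
#' @param a,b [trace_matrix()] objects with equal trace lengths (at least 2
#'   traces each).
#' @param max_perm Permutation budget; exhaustive enumeration is used when it
#'   covers all distinct assignments.
#' @param tail `"two"` or `"one"`.
#' @param seed Optional seed for the random-permutation mode.
#' @return A `permutation_result`: list with `p_values`,
#'   `n_permutations_used`, `exhaustive`.
#' @examples
#' a <- trace_matrix(matrix(rnorm(20), 4, 5), fs = 10)
#' b <- trace_matrix(matrix(rnorm(20, 1), 4, 5), fs = 10)
#' permutation_test(a, b)$p_values
#' @export
permutation_test <- function(a, b, max_perm = 1000L, tail = c("two", "one"),
                             seed = NULL) {
  tail <- match.arg(tail)
  xa <- as_matrix_(a); xb <- as_matrix_(b)
  if (ncol(xa) != ncol(xb)) stop("'a' and 'b' must have equal trace lengths")
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 traces")
  N <- na + nb
  X <- rbind(xa, xb)
  n_comb <- choose(N, na)
  obs <- colMeans(xa) - colMeans(xb)
  eps <- 1e-12 * (1 + abs(obs))

  if (n_comb <= max_perm) {
    combos <- utils::combn(N, na)
    P <- matrix(-1 / nb, n_comb, N)
    for (i in seq_len(n_comb)) P[i, combos[, i]] <- 1 / na
    D <- P %*% X
    if (tail == "two") {
      p <- colMeans(abs(D) >= rep(abs(obs), each = n_comb) - rep(eps, each = n_comb))
    } else {
      p <- colMeans(D >= rep(obs, each = n_comb) - rep(eps, each = n_comb))
    }
    used <- n_comb; exhaustive <- TRUE
  } else {
    p <- with_seed_(seed, {
      P <- matrix(-1 / nb, max_perm, N)
      for (i in seq_len(max_perm)) P[i, sample.int(N, na)] <- 1 / na
      D <- P %*% X
      if (tail == "two") {
        b_cnt <- colSums(abs(D) >= rep(abs(obs), each = max_perm) - rep(eps, each = max_perm))
      } else {
        b_cnt <- colSums(D >= rep(obs, each = max_perm) - rep(eps, each = max_perm))
      }
      (b_cnt + 1) / (max_perm + 1)
    })
    used <- max_perm; exhaustive <- FALSE
  }
  structure(list(p_values = p, n_permutations_used = as.integer(used),
                 exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d timepoints, %d %s permutations, min p = %.4g\n",
              length(x$p_values), x$n_permutations_used,
              if (x$exhaustive) "exhaustive" else "random", min(x$p_values)))
  invisible(x)
}

#' Smallest p-value a permutation test can report
#'
#' With exhaustive enumeration of the `C(n_a + n_b, n_a)` distinct group
#' assignments, the smallest attainable p-value is the reciprocal of that
#' count (one-sided counting of the single extreme assignment: n = 4 per
#' group gives 1/70, about 0.014). The degenerate case of one trace per
#' group returns 1: both assignments produce the same absolute difference,
#' so no assignment is ever extreme.
#'
#' Note the two-sided test on distinct data with `n_a = n_b` pairs each
#' assignment with its mirror image, so its attainable minimum is twice this
#' value.
#'
#' @param n_a,n_b Group sizes (at least 1).
#' @return The minimum attainable p-value.
#' @examples
#' min_attainable_p(4, 4)  # ~0.014
#' @export
min_attainable_p <- function(n_a, n_b) {
  stopifnot(n_a >= 1L, n_b >= 1L)
  if (n_a == 1L && n_b == 1L) return(1)
  1 / choose(n_a + n_b, n_a)
}

#' Significance mask from permutation p-values
#'
#' Flags timepoints with `p < alpha` (strict inequality).
#'
#' @param result A [permutation_test()] result.
#' @param alpha Per-comparison significance level in (0, 1).
#' @return A [significance_mask()].
#' @export
significance_from_p <- function(result, alpha) {
  stopifnot(inherits(result, "permutation_result"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  significance_mask(result$p_values < alpha, alpha = alpha)
}
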