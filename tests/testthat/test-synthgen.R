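# A single shared noise ensemble keeps the heavier spectral and grand-mean
# checks to one generation pass.
set.seed(401)
noise_ens <- local({
  gp <- generator_params()
  t(vapply(seq_len(10000L), function(i) as.numeric(generate_noise_line(gp)),
           numeric(gp$n_points)))
})

test_that("transient magnitudes are half-normal", {
  set.seed(1)
  draws <- sample_transient_magnitude(1e5)
  expect_true(all(draws >= 0))
  se <- sqrt(1 - 2 / pi) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - sqrt(2 / pi)), 3 * se)
  set.seed(7); a <- sample_transient_magnitude(10)
  set.seed(7); b <- sample_transient_magnitude(10)
  expect_identical(a, b)
  expect_equal(mean(sample_transient_magnitude(1e4, scale = 2)),
               2 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("parabolic transient is symmetric with peak equal to the magnitude", {
  y <- parabolic_transient(1, 10, 1)
  expect_length(y, 10L)
  expect_equal(max(y), 1)
  expect_equal(y, rev(y), tolerance = 1e-12)
  expect_true(all(y > 0))          # near-zero edges, not exact zeros
  expect_lt(y[1], 0.25)
  expect_identical(parabolic_transient(1, 10, 0), rep(0, 10L))
  expect_equal(min(parabolic_transient(1, 10, -2)), -2)
  expect_error(parabolic_transient(0, 10, 1), "positive")
  expect_error(parabolic_transient(-1, 10, 1), "positive")
})

test_that("noise lines are zero-mean band-limited Gaussian noise", {
  gp <- generator_params()
  expect_identical(as.numeric(generate_noise_line(noiseless_params())),
                   rep(0, 100L))
  # pointwise grand mean compatible with a zero baseline
  sds <- apply(noise_ens, 2L, sd)
  z <- abs(colMeans(noise_ens)) / (sds / sqrt(nrow(noise_ens)))
  expect_true(all(z < 4))
  # pooled periodogram: negligible power beyond twice the cutoff
  pw <- rowMeans(Mod(stats::mvfft(t(noise_ens)))^2)
  freq <- (seq_len(gp$n_points) - 1L) * gp$fs / gp$n_points
  half <- freq <= gp$fs / 2
  below <- mean(pw[half & freq > 0 & freq < gp$lowpass_hz])
  above <- mean(pw[half & freq > 2 * gp$lowpass_hz])
  expect_lt(above, 0.05 * below)
})

test_that("low-pass filtering is zero-phase", {
  imp <- c(rep(0, 50), 1, rep(0, 49))
  out <- lowpass_filter(imp, fs = 10, cutoff = 2)
  expect_identical(which.max(out), which.max(imp))
  m <- lowpass_filter(rbind(imp, imp), fs = 10, cutoff = 2)
  expect_equal(m[1, ], out)
})

test_that("ERT lines carry the transient at the halfway window", {
  gp <- noiseless_params()
  set.seed(2)
  v <- as.numeric(generate_line("ert", gp, magnitude = 1))
  expect_identical(which(v != 0), 51:60)
  expect_equal(v[51:60], parabolic_transient(1, 10, 1))
  expect_error(generate_line("bogus", gp), "arg")
  # mean peak height across draws matches the half-normal mean
  set.seed(3)
  peaks <- vapply(seq_len(1e4), function(i) generate_line("ert", gp)[55],
                  numeric(1L))
  se <- sqrt(1 - 2 / pi) / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - sqrt(2 / pi)), 3 * se)
})

test_that("null lines carry unrelated transients at the stated rate", {
  gp <- noiseless_params()
  set.seed(4)
  lines <- t(vapply(seq_len(1e4), function(i) as.numeric(generate_line("null", gp)),
                    numeric(100L)))
  has <- rowSums(lines != 0) > 0
  se <- sqrt(0.25 / length(has))
  expect_lt(abs(mean(has) - 0.5), 3 * se)
  # transients fit wholly inside the window and occupy 10 samples
  expect_true(all(rowSums(lines != 0) %in% c(0L, 10L)))
  # signed null transients: both directions occur, mean ~ 0 at interior points
  signs <- sign(rowSums(lines))
  expect_gt(sum(signs > 0), 0)
  expect_gt(sum(signs < 0), 0)
})

test_that("subjects average a uniform number of lines", {
  gp <- noiseless_params()
  set.seed(5)
  ks <- vapply(seq_len(1e4), function(i)
    attr(generate_subject("null", gp), "n_lines"), integer(1L))
  expect_true(all(ks %in% 1:31))
  gof <- stats::chisq.test(table(factor(ks, levels = 1:31)))
  expect_gt(gof$p.value, 0.001)
  # degenerate range: a subject is a single line
  gp1 <- noiseless_params(lines_per_subject_range = c(1L, 1L))
  set.seed(6)
  s <- generate_subject("ert", gp1)
  expect_identical(attr(s, "n_lines"), 1L)
  nz <- which(as.numeric(s) != 0)
  expect_identical(nz, 51:60)
  expect_equal(as.numeric(s)[nz] / max(as.numeric(s)),
               parabolic_transient(1, 10, 1))
})

test_that("averaging more lines shrinks subject variance", {
  set.seed(8)
  v1 <- apply(t(vapply(seq_len(80), function(i)
    as.numeric(generate_subject("null", generator_params(lines_per_subject_range = c(1L, 1L)))),
    numeric(100L))), 2L, var)
  v31 <- apply(t(vapply(seq_len(80), function(i)
    as.numeric(generate_subject("null", generator_params(lines_per_subject_range = c(31L, 31L)))),
    numeric(100L))), 2L, var)
  expect_lt(mean(v31), mean(v1))
})

test_that("populations are reproducible and shaped by the transient", {
  gp <- small_params(seed = 99L)
  p1 <- generate_populations(gp)
  p2 <- generate_populations(gp)
  expect_identical(p1, p2)
  expect_identical(nrow(p1$null), gp$population_subjects)
  expect_identical(nrow(p1$ert), gp$population_subjects)
  expect_identical(attr(p1$ert, "condition"), "ert")
  # the ERT bump is confined to the halfway 1-s window (+/- 0.5 s margin)
  m <- colMeans(p1$ert)
  supp <- transient_support(gp)
  margin <- unique(pmin(pmax(c(outer(supp, -5:5, "+")), 1L), gp$n_points))
  expect_gt(max(abs(m[supp])), max(abs(m[-margin])))
})

test_that("outside the transient support the ERT ensemble matches the null", {
  # independently generated subjects (population subjects share lines, which
  # would violate the t-test's independence assumption)
  gp <- generator_params()
  set.seed(123)
  ert <- t(vapply(seq_len(250), function(i)
    as.numeric(generate_subject("ert", gp)), numeric(100L)))
  nul <- t(vapply(seq_len(250), function(i)
    as.numeric(generate_subject("null", gp)), numeric(100L)))
  out_idx <- setdiff(seq_len(gp$n_points), transient_support(gp))
  pv <- vapply(out_idx, function(j)
    stats::t.test(ert[, j], nul[, j])$p.value, numeric(1L))
  expect_true(all(stats::p.adjust(pv, "bonferroni") > 0.001))
  # and inside the support the difference is unmistakable
  expect_lt(stats::t.test(ert[, 55], nul[, 55])$p.value, 1e-10)
})

test_that("generator parameters are validated", {
  expect_error(generator_params(lowpass_hz = 6), "lowpass")
  expect_error(generator_params(transient_duration = 0.1), "2 samples")
  expect_error(generator_params(null_transient_prob = 1.5), "probability")
  expect_error(generator_params(lines_per_subject_range = c(5L, 1L)), "ordered")
  expect_error(generator_params(transient_duration = 20), "fit")
  expect_identical(transient_support(generator_params()), 51:60)
})
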