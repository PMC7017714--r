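# Small parameter sets used across tests: standard-shaped traces but reduced
# population sizes so unit tests stay fast.
small_params <- function(...) {
  generator_params(population_lines = 300L, population_subjects = 60L, ...)
}

noiseless_params <- function(...) {
  generator_params(noise_power = 0, ...)
}

# Noise-free "populations" with a unit-magnitude transient: every ERT subject
# is the same parabola, every null subject is flat zero.
constant_populations <- function(gp = generator_params(), n_subjects = 60L) {
  tr <- rep(0, gp$n_points)
  tr[transient_support(gp)] <- parabolic_transient(gp$transient_duration, gp$fs, 1)
  list(
    null = trace_matrix(matrix(0, n_subjects, gp$n_points), fs = gp$fs,
                        condition = "null"),
    ert = trace_matrix(matrix(tr, n_subjects, gp$n_points, byrow = TRUE),
                       fs = gp$fs, condition = "ert"))
}

normal_tm <- function(n, t, fs = 10, mean = 0, sd = 1) {
  trace_matrix(matrix(stats::rnorm(n * t, mean, sd), n, t), fs = fs)
}
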