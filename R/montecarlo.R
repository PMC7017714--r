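#' Configuration of a Monte Carlo detection study
#'
#' Defines the simulation grid: sample sizes drawn per simulation,
#' confidence levels, consecutive-threshold fractions, detection methods,
#' and the generator producing the subject populations.
#'
#' @param sample_sizes Subjects drawn per simulation (each at least 2;
#'   permutation cells want at least 4 for a usable minimum p).
#' @param levels Confidence levels, e.g. `c(0.95, 0.99)`.
#' @param threshold_fractions Consecutive-threshold fractions of the
#'   low-pass window (see [threshold_length()]).
#' @param methods Subset of `"tci"`, `"bci"`, `"perm"`.
#' @param n_sims Simulations per (method, n, level) cell.
#' @param n_boot Bootstrap resamples per bCI analysis.
#' @param max_perm Permutation budget per permutation analysis.
#' @param generator A [generator_params()] object.
#' @param seed Master seed; populations and every trial derive their streams
#'   from it.
#' @return A `study_config` list.
#' @export
study_config <- function(sample_sizes = c(5L, 10L, 20L, 40L),
                         levels = c(0.95, 0.99),
                         threshold_fractions = c(0, 0.5, 1),
                         methods = c("tci", "bci", "perm"),
                         n_sims = 1000L, n_boot = 1000L, max_perm = 1000L,
                         generator = generator_params(), seed = NULL) {
  methods <- match.arg(methods, c("tci", "bci", "perm"), several.ok = TRUE)
  cfg <- list(sample_sizes = as.integer(sample_sizes), levels = levels,
              threshold_fractions = threshold_fractions, methods = methods,
              n_sims = as.integer(n_sims), n_boot = as.integer(n_boot),
              max_perm = as.integer(max_perm), generator = generator,
              seed = seed)
  if (any(cfg$sample_sizes < 2L)) stop("every sample size must be at least 2")
  if (cfg$n_sims < 1L) stop("'n_sims' must be at least 1")
  if (any(cfg$levels <= 0 | cfg$levels >= 1)) stop("levels must lie in (0, 1)")
  if (any(cfg$threshold_fractions < 0)) stop("threshold fractions must be >= 0")
  stopifnot(inherits(generator, "generator_params"))
  class(cfg) <- "study_config"
  cfg
}

mask_for_method_ <- function(method, sample, baseline, level, n_boot, max_perm) {
  switch(method,
    tci  = significance_from_ci(t_interval(sample, level)),
    bci  = significance_from_ci(bootstrap_interval(sample, level,
                                                   n_boot = n_boot, expand = TRUE)),
    perm = significance_from_p(permutation_test(sample, baseline,
                                                max_perm = max_perm), 1 - level),
    stop("unknown method: ", method))
}

#' Run one Monte Carlo trial
#'
#' Draws an n-subject sample (without replacement) from each condition's
#' population, computes the method's raw significance mask per condition
#' (CI methods against a null of 0; the permutation method against a
#' freshly drawn, disjoint n-subject baseline sample from the null
#' population), applies each requested consecutive threshold, and scores:
#' the null-condition sample for any false positive anywhere in the window,
#' and the ERT-condition sample for the fraction of the transient-support
#' timepoints flagged (flags survive thresholding globally first and are
#' then intersected with the support).
#'
#' @param null_pop,ert_pop Subject populations ([trace_matrix()] objects).
#' @param method `"tci"`, `"bci"`, or `"perm"`.
#' @param n Subjects sampled per condition.
#' @param level Confidence level.
#' @param threshold_samples Vector of minimum run lengths to score (samples).
#' @param support Column indices of the true transient (see
#'   [transient_support()]).
#' @param n_boot Bootstrap resamples (bCI only).
#' @param max_perm Permutation budget (permutation only).
#' @param seed Optional seed for this trial's draws.
#' @return A data frame with one row per condition x threshold: columns
#'   `condition`, `method`, `n`, `level`, `threshold_samples`,
#'   `any_false_positive`, `ert_fraction_rejected`, `detected` (the last two
#'   `NA` for the null condition, the first `NA` for the ERT condition).
#' @export
run_trial <- function(null_pop, ert_pop, method, n, level, threshold_samples,
                      support, n_boot = 1000L, max_perm = 1000L, seed = NULL) {
  npop <- nrow(null_pop)
  needed <- if (method == "perm") 2L * n else n
  if (needed > npop || n > nrow(ert_pop))
    stop("population too small to draw ", n, " subjects (plus baseline)")
  with_seed_(seed, {
    null_idx <- sample.int(npop, n)
    ert_smp <- ert_pop[sample.int(nrow(ert_pop), n), , drop = FALSE]
    null_smp <- null_pop[null_idx, , drop = FALSE]
    baseline <- NULL
    if (method == "perm") {
      avail <- setdiff(seq_len(npop), null_idx)
      baseline <- null_pop[sample(avail, n), , drop = FALSE]
    }
    m_null <- mask_for_method_(method, null_smp, baseline, level, n_boot, max_perm)
    m_ert  <- mask_for_method_(method, ert_smp, baseline, level, n_boot, max_perm)
    out <- lapply(threshold_samples, function(k) {
      fn <- apply_consecutive_threshold(m_null, k)$flags
      fe <- apply_consecutive_threshold(m_ert, k)$flags
      frac <- mean(fe[support])
      data.frame(
        condition = c("null", "ert"), method = method, n = n, level = level,
        threshold_samples = as.integer(k),
        any_false_positive = c(any(fn), NA),
        ert_fraction_rejected = c(NA, frac),
        detected = c(NA, frac > 0))
    })
    do.call(rbind, out)
  })
}

#' Run a Monte Carlo detection study
#'
#' Generates (or reuses) the null and ERT subject populations, then for every
#' (method, n, level) cell runs `n_sims` independent trials via [run_trial()],
#' scoring all requested consecutive thresholds on each trial's raw mask.
#' Every trial's RNG stream is derived from the master seed through a
#' per-cell seed table, so the results are reproducible and independent of
#' execution order.
#'
#' @param config A [study_config()].
#' @param populations Optional pre-generated `list(null =, ert =)` population
#'   pair (as returned by [generate_populations()]); generated from
#'   `config$generator` when omitted.
#' @return A `montecarlo_summary` data frame with one row per
#'   (method, n, level, threshold) cell: columns `fwer` (proportion of null
#'   simulations with any false positive), `mean_correct_reject` (mean
#'   fraction of the transient support flagged), `miss_rate` (proportion of
#'   ERT simulations with nothing flagged in the support), and `n_sims`.
#' @examples
#' \donttest{
#' gp <- generator_params(population_lines = 500, population_subjects = 100,
#'                        seed = 1)
#' cfg <- study_config(sample_sizes = 8, levels = 0.95, n_sims = 50,
#'                     generator = gp, seed = 1)
#' run_study(cfg)
#' }
#' @export
run_study <- function(config, populations = NULL) {
  stopifnot(inherits(config, "study_config"))
  gp <- config$generator
  with_seed_(config$seed, {
    if (is.null(populations)) {
      if (is.null(gp$seed)) gp$seed <- sample.int(2^31 - 2, 1L)
      populations <- generate_populations(gp)
    }
    ths <- vapply(config$threshold_fractions, threshold_length,
                  integer(1L), fs = gp$fs, lowpass_hz = gp$lowpass_hz)
    support <- transient_support(gp)
    cells <- expand.grid(method = config$methods, n = config$sample_sizes,
                         level = config$levels, stringsAsFactors = FALSE)
    seed_tab <- matrix(sample.int(2^31 - 2, nrow(cells) * config$n_sims),
                       nrow(cells), config$n_sims)
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      trials <- lapply(seq_len(config$n_sims), function(s) {
        run_trial(populations$null, populations$ert,
                  method = cells$method[ci], n = cells$n[ci],
                  level = cells$level[ci], threshold_samples = ths,
                  support = support, n_boot = config$n_boot,
                  max_perm = config$max_perm, seed = seed_tab[ci, s])
      })
      rows[[ci]] <- do.call(rbind, trials)
    }
    raw <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(
      raw, list(raw$method, raw$n, raw$level, raw$threshold_samples), drop = TRUE),
      function(d) {
        nullr <- d[d$condition == "null", ]
        ertr <- d[d$condition == "ert", ]
        data.frame(method = d$method[1L], n = d$n[1L], level = d$level[1L],
                   threshold_samples = d$threshold_samples[1L],
                   fwer = mean(nullr$any_false_positive),
                   mean_correct_reject = mean(ertr$ert_fraction_rejected),
                   miss_rate = mean(!ertr$detected),
                   n_sims = nrow(ertr))
      }))
    agg$threshold_fraction <- config$threshold_fractions[match(
      agg$threshold_samples, ths)]
    agg <- agg[order(agg$method, agg$n, agg$level, agg$threshold_samples),
               c("method", "n", "level", "threshold_fraction",
                 "threshold_samples", "fwer", "mean_correct_reject",
                 "miss_rate", "n_sims")]
    rownames(agg) <- NULL
    structure(agg, config = config,
              class = c("montecarlo_summary", "data.frame"))
  })
}

#' @export
print.montecarlo_summary <- function(x, ...) {
  cat("Monte Carlo detection study\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
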