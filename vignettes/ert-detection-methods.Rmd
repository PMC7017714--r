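---
title: "Detecting event-related transients with waveform statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting event-related transients with waveform statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ertwave)
```

## The problem

Fiber photometry experiments ask whether a neural population shows a phasic
change in activity — an event-related transient (ERT) — time-locked to some
behavioral or environmental event. The classical workflow summarizes the
peri-event dF waveform into a single number (AUC, peak dF) over a
researcher-chosen window and tests that summary. This discards temporal
information and invites post hoc window selection. The alternative
implemented here analyzes *every timepoint* of the peri-event window and
controls the resulting multiplicity with a consecutive-significance
threshold instead of a per-comparison correction.

`ertwave` provides three pointwise detectors, a run-length threshold, a
synthetic-signal generator, and a Monte Carlo harness that measures how the
combination behaves.

## Detection methods

Throughout, the input is a `trace_matrix`: one row per subject (or trial),
one column per timepoint, with a sampling rate `fs`.

**Parametric t interval (tCI).** At each timepoint,
`mean ± SEM · t_crit` with `df = n − 1` and a two-sided critical value
(`t_interval()`). A timepoint is flagged when the interval excludes the
null value (dF = 0 after proper normalization); an interval that merely
touches the null is counted as containing it.

**Expanded percentile bootstrap interval (bCI).** Whole traces are
resampled with replacement (1,000 times by default) and the pointwise
bounds are percentiles of the bootstrap means — 2.5/97.5 at the 95% level,
0.5/99.5 at 99% (`bootstrap_interval()`). Percentile intervals are too
narrow at small n by an average factor of `(n−1)/n`, so each bound is moved
away from the sample mean by `n/(n−1)`:
`bound' = mean + (bound − mean) · n/(n−1)`. Resampling whole rows (not
per-timepoint values) preserves within-trace autocorrelation.

**Permutation test.** Two samples (e.g., an analysis sample and a baseline
sample) are compared by reassigning whole traces between groups
(`permutation_test()`). When the number of distinct assignments
`C(n_a+n_b, n_a)` is within the permutation budget, all of them are
enumerated — including the observed one — so p-values are exact and never
zero; otherwise random reassignments are drawn and `p = (b+1)/(m+1)`. The
default statistic is the absolute mean difference (two-sided), with a
one-sided option. The smallest p an exhaustive test can report is
`1/C(n_a+n_b, n_a)` under one-sided counting (`min_attainable_p()`; 1/70 ≈
0.014 at n = 4 per group); a two-sided test on distinct balanced data pairs
each assignment with its mirror image and therefore bottoms out at twice
that value. We report the one-sided count, the convention under which the
n = 4 example is usually quoted, and expose the tail choice explicitly.

**Consecutive threshold.** Noise produces brief, unaligned blips of
significance; true transients produce sustained runs. A mask is therefore
filtered to keep only maximal runs of at least `k` consecutive significant
samples (`apply_consecutive_threshold()`), with `k` tied to the low-pass
window: `k = ceiling(fraction · fs / lowpass_hz)` (`threshold_length()`).
At 10 Hz sampling with a 2 Hz cutoff the window is 0.5 s, so the
half-window threshold is 3 samples and the full-window threshold is 5.
Runs are counted regardless of effect direction by default (a run crossing
from significantly-above to significantly-below null without a gap is one
run); passing a direction vector splits runs at sign changes.

## The synthetic-signal generator

`generator_params()` describes the generative model used for calibration
studies:

* a peri-event window of `n_points = 100` samples at `fs = 10` Hz (10 s);
* white Gaussian noise of variance `noise_power = 0.1`, low-pass filtered
  at `lowpass_hz = 2` Hz with a zero-phase (forward–backward) 2nd-order
  Butterworth filter;
* a 1-s parabolic transient sampled on a symmetric half-offset grid and
  rescaled so its sampled peak equals the drawn magnitude; magnitudes are
  half-normal (`|z|`, mean ≈ 0.798 dF);
* ERT-condition lines always carry the transient starting at the halfway
  point of the window (samples 51–60); null-condition lines carry, with
  probability 0.5, an *unrelated* transient at a uniform-random position
  that fits wholly inside the window;
* subjects are means of `k` lines, `k` uniform on 1–31; populations hold
  10,000 lines and 1,000 subjects per condition.

Design choices worth spelling out:

* **Noise scale.** "Noise at 10 dB" against a zero baseline is read as the
  additive-noise convention with a 0 dBW reference, i.e., pre-filter
  variance 0.1. The scale is exposed (`noise_power`) so users can
  recalibrate to their own recordings; detection and error rates depend on
  it jointly with the magnitude scale.
* **Signed null transients.** Unrelated transients are excitatory or
  inhibitory with equal probability (`signed_null_transients = TRUE`).
  Strictly positive unrelated transients would give the null population a
  positive pointwise mean of roughly
  `0.5 · E|z| · mean(parabola) · duration/window ≈ 0.03` dF, a bias that no
  one-sample interval can distinguish from signal: the null-condition
  grand mean would no longer be zero and family-wise error control against
  a null of 0 would fail at any realistic noise level, for any n. Signed
  transients keep the null population mean at zero, which is also the
  property the detectors are being calibrated against.
* **Filter placement.** Noise is filtered, then the transient is added
  unfiltered, so the transient support is exactly its nominal 10 samples.
  The filter is zero-phase, so nothing is delayed.

What the generator does *not* emulate: biosensor kinetics (GCaMP rise and
decay would smear and lag the transient), bleaching and slow drifts,
isosbestic correction, or the computation of dF/F from raw fluorescence.
Passing calibration under this model therefore says how the statistics
behave on band-limited Gaussian noise with additive transients — not that a
particular recording pipeline is sound.

## The Monte Carlo harness

`run_study()` reproduces the calibration design: draw `n` subjects per
condition (without replacement) from the populations, analyze each sample
with each method, apply each consecutive threshold to the raw mask, and
aggregate over simulations:

* **FWER** — proportion of null-condition simulations with *any*
  significant flag anywhere in the 100-sample window;
* **mean correct-reject** — mean fraction of the 10 transient-support
  samples flagged in ERT-condition simulations (flags survive thresholding
  globally first, then are intersected with the support, so a run
  straddling the support boundary contributes its in-support samples);
* **miss rate** — proportion of ERT simulations with nothing flagged inside
  the support.

CI methods test against the null of 0. The permutation method needs a
comparison distribution, so each trial draws an additional baseline sample
from the null population, disjoint from that trial's analysis sample.
Every trial's RNG stream derives from the master seed through a per-cell
seed table, making cells independently reproducible.

Default problem sizes in the shipped tests and the acceptance script are
500 simulations for the n = 10 / 95% cells and 1,000 for the n = 5 / 99%
cells — enough that binomial error is several times smaller than every
margin asserted — rather than the full n = 5–100 grid, which the same
functions will run if asked.

## Numerical choices

* Percentiles use linear interpolation between order statistics
  (`stats::quantile`, type 7).
* CI endpoints are closed; touching the null is not significant.
  Permutation flags require `p < alpha` strictly.
* Permutation tie comparisons use a relative `1e-12` tolerance so that
  floating-point noise cannot drop the observed assignment from its own
  tie set.
* Two-sample t intervals use Welch degrees of freedom; at zero pooled
  variance the interval degenerates to the point difference.
* Bootstrap weights are accumulated into a weight matrix so all bootstrap
  means come from one matrix product; with `n_boot = 1000` the quantile
  noise on the bounds is far below the effects studied.

## Behavior under the default model, and known limitations

With the defaults, the package's own calibration (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) shows the
expected picture: without a consecutive threshold every method's FWER is
far above the nominal rate; the full 5-sample threshold brings tCI and the
permutation test to or below it, and barely changes detection, which
averages well above half of the transient for every method at n = 10.

Two aspects of the method comparison deserve honest caveats:

* The expanded percentile bootstrap is anti-conservative pointwise at
  moderate n (per-point Type I ≈ 0.07 at n = 10, 95%), and the full
  5-sample threshold leaves its FWER somewhat above the nominal 0.05
  (≈ 0.09–0.10 under the defaults) even though the same threshold controls
  tCI and permutation FWER. Expansion by `n/(n−1)` narrows but does not
  close the gap to the t critical ratio. Users who need strict FWER
  control at small-to-moderate n should prefer tCI or the permutation
  test, or lengthen the threshold.
* At n = 5 and the 99% level with the full threshold, the bootstrap CI is
  clearly the most sensitive detector (miss rate well under 1%). In this
  reconstruction the permutation test (miss ≈ 3–5%) sits *between* the
  bootstrap and the t interval (miss ≈ 10%), whose `t_crit(4) = 4.60`
  makes it the widest interval at that extreme level; orderings at such
  small n are sensitive to the exact noise-to-magnitude ratio of the
  generative model.

Also note that subjects within one generated population share underlying
lines and are therefore weakly correlated; analyses that assume
independent subjects (as the detectors do) see a slightly optimistic
effective n when samples are drawn from small populations. The defaults
(10,000 lines, 1,000 subjects, samples of 5–100) keep this effect
negligible.

## A worked example

```{r, eval = FALSE}
library(ertwave)

gp <- generator_params(seed = 1)
pops <- generate_populations(gp)

# analyze one n = 10 ERT sample against the null of 0
smp <- pops$ert[sample(nrow(pops$ert), 10), ]
ci <- t_interval(smp, level = 0.95)
mask <- significance_from_ci(ci, null_value = 0)
k <- threshold_length(fs = 10, lowpass_hz = 2, fraction = 1)
thr <- apply_consecutive_threshold(mask, k)
significant_runs(thr, fs = 10, center = ci$center)

# calibrate: one Monte Carlo cell
cfg <- study_config(sample_sizes = 10, levels = 0.95,
                    threshold_fractions = c(0, 1), n_sims = 200,
                    generator = gp, seed = 2)
run_study(cfg, populations = pops)
```
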