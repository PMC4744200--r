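---
title: "Modelling telomere attrition in hematopoietic stem cells: methods and design choices"
author: "telodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling telomere attrition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Hematopoietic stem cells (HSCs) divide either *asymmetrically* — one
daughter stays a stem cell, the other commits and leaves the pool — or
*symmetrically*, producing two stem cells. Every division shortens the
daughters' mean telomere length by a fixed amount `delta_c` (of the order
of 50 bp), because DNA polymerase cannot fully copy chromosome ends. A
cell whose telomeres are exhausted enters permanent cycle arrest (its
Hayflick limit). `telodyn` tracks cells by their division count: state
`i` holds cells that have divided `i` times, with remaining length
`c0 - i * delta_c`, and state `c_states = c0 / delta_c` is absorbing.

Two division regimes are distinguished:

* **Model 1 (asymmetric only, `p = 0`).** The pool size is conserved at
  `N0`. With the population dividing `r` times per year (per-cell rate
  `r / N0`), the expected occupancy of state `i < c` at time `t` is a
  truncated Poisson distribution with parameter `x = r t / N0`:
  `N_i(t) = N0 * dpois(i, x)`, with the arrest state holding the
  remainder. See `occupancy_model1()`.
* **Model 2 (symmetric self-renewal with probability `p`).** Each
  division is symmetric with probability `p`, so the pool grows linearly,
  `N(t) = N0 * t*` with rescaled time `t* = (r p / N0) t + 1`, and the
  per-cell division rate falls as `r / N(t)` (the population maintains a
  constant output of committed cells). The occupancies become a
  generalised Poisson wave: with `rho = (1 + p) / p` and
  `lambda = rho * ln(t*)`,
  `N_i(t) = N0 * t* * dpois(i, lambda)` for `i < c`. See
  `occupancy_model2()`.

The model-2 normalisation deserves a note. Writing the solution as
`(N0/i!) * rho^i * ln^i(t*) * t*^(-1/p)` makes three independent checks
come out exactly: the total equals `N0 * t*` (because
`t*^(-1/p) = e^(-lambda) * t*`), the `p -> 0` limit reproduces model 1
term by term, and differentiating the state occupancy in time gives the
wave-maximum time `t_max(i) = N0 (e^(i p) - 1) / (r p)`. These three
identities are enforced as tests rather than trusted; any other exponent
fails all three.

Viewed along the telomere-length axis the occupancy vector is a
*travelling wave*: it starts concentrated at `c0`, moves towards shorter
lengths, and broadens. Intermediate states rise to a maximum and empty
again; under model 1 the peak of state `i` is `N0 * dpois(i, i)` (about
`N0 / sqrt(2 pi i)` by Stirling's formula) at `t_max = i N0 / r`, while
under model 2 the peak `~ N0 (1+p)^i / sqrt(2 pi i)` decays much more
slowly because the growing pool keeps re-populating the wave
(`wave_max()`).

### Moments

Both models reduce, after normalising by the (growing) total, to a
truncated Poisson with an effective parameter `x_eff` (`r t / N0` or
`rho ln t*`), so the mean telomere length has a single closed form built
from the regularised incomplete gamma function (`mean_tl_exact()`). Two
working approximations cover the pre-exhaustion regime used for cohort
fitting (`mean_tl_approx()`):

* model 1: linear decay `E[c](t) = c0 - kappa * t`,
* model 2: logarithmic decay
  `E[c](t) = c0 - delta_c * rho * ln((kappa / delta_c) p t + 1)`,

with `kappa = delta_c * r / N0` the composite loss rate. The variance
grows linearly (`sigma = delta_c * sqrt(r t / N0)`, `sd_approx()`) until
arrest accumulates, then collapses; the exact second moment and the MGF
are available for model 1 (`variance_model1()`, `mgf_model1()`) and are
validated against brute-force sums over the occupancy vector.

### Identifiability and the two reference scales

Population-average telomere data identify only composites: the curve
`c0 - A ln(b t + 1)` has three observable parameters (`c0`, amplitude
`A`, timescale `b`), and any mechanistic set with
`A = delta_c_ref (1+p)/p` and `b = (kappa/delta_c_ref) p` produces the
same curve. The package therefore separates two conventions:

* **Cohort scale (`delta_c = 1` kbp, the default in `mean_tl_approx()`,
  `loss_rate()`, `fit_mean_model()`, `abc_rejection()`,
  `generate_population()`).** Under this reference the canonical
  parameter values — `kappa ~ 0.075` kbp/year, `c0 ~ 10.4` kbp,
  `p ~ 0.35` — yield the familiar phenomenology: roughly 100 bp/year of
  loss at birth, about 50 bp/year in adults, a pronounced logarithmic
  decline through childhood, and a total loss of ~4.5 kbp by age 85.
  This is the scale on which the cohort fits and ABC posteriors are
  reported.
* **Mechanistic / single-cell scale (`delta_c = 0.05` kbp/division,
  the default in `stem_cell_params()`, `telomere_density()`,
  `generate_individual()`, `fit_distribution()`).** Per-cell data
  resolve the division-count distribution itself, so here `delta_c` is
  the literal ~50 bp lost per division.

The two `p` values that come out of the two pipelines (population-level
`p ~ 0.3` versus per-snapshot `p` of order 0.01) are *not* the same
quantity under different noise — they live on different reference scales
and the package makes no attempt to merge them.

## The stochastic simulator

`simulate_population()` is an event-driven, individual-based
implementation whose ensemble mean is the exact stochastic counterpart of
the occupancy equations: every non-arrested cell divides at per-cell rate
`r / (N0 + r p t)` (model 1: `r / N0`), the mother is removed, and one or
two daughters enter the next state. Waiting times for the inhomogeneous
rate have the closed form
`dt = ((N0 + r p t) e^(E p / M) - N0) / (r p) - t` for `E ~ Exp(1)` and
`M` non-arrested cells. Because the expectation of a linear birth process
with deterministic time-varying rates satisfies the mean-field equations
exactly, ensemble means converge to `occupancy_model1()` /
`occupancy_model2()` at the Monte-Carlo rate for every pre-arrest state —
this is tested at `N0 = 100`, `c_states = 7`, 1000 replicates.

An alternative timing, `timing = "constant_output"`, pins the *total*
division rate at exactly `r` regardless of pool composition. The two
timings agree while arrest is negligible (the regime in which the
constant-output idealisation is meant), but once a substantial fraction
of cells arrest, the constant-rate variant makes the survivors divide
faster than the mean-field equations assume and the late-time occupancies
drift away from the analytic forms. It is therefore a sensitivity check,
not the default.

## Synthetic data

No clinical measurements ship with the package; both generators produce
data with the statistical structure the inference layer assumes, plus the
generating truth as an attribute, so every fit can be scored against a
known answer.

* `generate_population()` emulates a Flow-FISH cohort: `n_subjects`
  (default 356) with ages uniform on 0–85 (a `"cohort"` preset instead
  pins a cord-blood-like 13% of subjects at age 0), an individual
  baseline `c0_i ~ N(c0, baseline_sd)`, and measured mean
  `curve(age; kappa, c0_i, p) + N(0, s)` with
  `s^2 = noise_sd^2 + process_delta_c * kappa * age` — the second term is
  the division process's own variance, which makes the cohort SD grow
  with the square root of age. Defaults `baseline_sd = 0.5`,
  `noise_sd = 0.3` kbp are design choices for a plausible Flow-FISH
  spread, not measured quantities; instrument noise magnitudes for
  Flow-FISH are not published alongside the method. With
  `include_process_sd = FALSE` and both SDs zero, records lie exactly on
  the generating curve (used for the noiseless-identifiability tests).
* `generate_individual()` emulates a Q-FISH snapshot: per-cell division
  counts `k ~ Poisson(rho ln t*)` truncated at arrest, lengths
  `c0 - k delta_c` plus cell-level Gaussian noise (`cell_noise_sd = 1.0`
  kbp by default — again a design default). An optional `per_spot` mode
  instead averages 184 log-normal spot signals per cell, mimicking the
  per-telomere measurement before cell-level averaging.

What the generators deliberately do **not** emulate: fluorescence
calibration drift, image-segmentation artefacts, batch effects between
instruments, non-uniform age recruitment beyond the cord-blood preset,
and any telomerase-mediated re-elongation. Passing recovery tests on
these data therefore demonstrates correctness of the estimators under the
model's own assumptions, not robustness to every artefact of real
cytometry.

## Inference

* **`r_squared()`** is the standard squared-residual coefficient of
  determination. (Written without the squares the two sums would
  sign-cancel and the statistic would not be bounded by 1; the squared
  form is the only one under which acceptance thresholds like "discard
  below 0.53" are meaningful.)
* **`fit_mean_model()`** fits the linear (model 1, exact linear algebra)
  or logarithmic (model 2) decay by bounded Levenberg–Marquardt least
  squares with five starts spread over `p`; ties in RSS resolve to the
  lowest `p` to avoid the near-flat boundary at `p ~ 0`. The Gaussian
  log-likelihood `-n/2 (ln(2 pi RSS/n) + 1)` counts sigma as a
  parameter, so `k` = 3 (model 1), 4 (model 2), 8 (two-phase); relative
  likelihoods `exp((AIC_min - AIC)/2)` are invariant to the additive
  constant of that convention. CIs are percentile bootstrap over
  records (default 1000 resamples).
* **`fit_two_phase()`** gives each phase its own `(kappa, c0, p)` and a
  transition age `tT`; phase 2 restarts its clock (and initial length) at
  `tT`, continuity deliberately not enforced, matching the 7-structural-
  parameter count. `tT` is profiled over an annual grid; candidates
  leaving fewer than 3 records in a phase are rejected, and a candidate
  at or past the oldest subject degenerates to the single-phase fit.
* **`abc_rejection()`** draws from uniform priors
  (`kappa in [0, 0.2]` kbp/year, `c0 in [7, 15]` kbp, `p in [0, 1]`,
  `tT in [0, 80]` years), scores each draw's curve by `R^2` against the
  cohort, and keeps draws with `R^2 >= max - 0.001` by default. The
  relative rule reproduces the *procedure* of cutting just below the
  observed maximum; absolute cutoffs can be supplied when a fixed
  threshold is wanted. Draw counts are a parameter: published analyses
  of this kind use 10^8–10^9 draws; the package's desk-scale default is
  10^5 and the acceptance experiments use 10^6, which already localises
  the posterior to a few-percent neighbourhood of the least-squares
  optimum at cohort size 356.
* **`fit_distribution()`** fits the snapshot density to a per-cell
  histogram. The density's shape depends on `(t_star, p)` only through
  `lambda = rho ln t*`, so the three-parameter problem is exactly flat
  along a ridge; the implementation profiles the ridge out, optimising
  `(log lambda, c0)` with method-of-moments anchors (`lambda delta_c^2`
  equals the process variance), and reports the ridge representative at
  the lowest admissible `p`, under which the derived loss rate equals its
  stable limit `1000 delta_c lambda / age` bp/year. Every result carries
  `degenerate = TRUE` as a reminder that `t_star` and `p` individually
  are not identified by a single snapshot. Binning uses the
  Freedman–Diaconis width capped to `[2 delta_c, 0.5]` kbp: a fixed
  0.5-kbp bin would blur the noiseless wave (SD ~0.3 kbp) into two bins
  and destroy the `lambda`/`c0` separation, while bins below the
  division lattice produce comb artefacts. Histogram breaks are offset
  by half a lattice step for the same reason. When the cell-level
  measurement noise is known (as it is for synthetic data and for
  calibrated instruments), `noise_sd` convolves the model density with
  the corresponding Gaussian before fitting; without it, estimates from
  noisy data are structurally biased towards wider, shifted waves.
* **`cohort_loss_rate_trend()`** regresses the derived per-individual
  loss rates on age within each cell type. The slope is a trend
  indicator only; nothing in the model makes the age dependence linear.

## Numerical choices

* Model-2 expressions switch to their analytic `p -> 0` limits below
  `p = 1e-6`; elsewhere `log1p` keeps `rho * ln t*` accurate for tiny
  `p t`.
* Poisson terms with large state indices are evaluated in log space
  (`exp(k ln lambda - lambda - lgamma(k+1))`).
* `telomere_density()` generalises the factorial to continuous lengths
  via the gamma function; mass at division counts beyond arrest is
  truncated and the density renormalised over `[0, c0]` (trapezoidal
  rule on a 4096-point grid, accurate to well below the 1e-6
  normalisation tolerance). At `t* = 1` the distribution is degenerate
  at `c0` and is represented by all mass in the first division cell.
* The exact variance is computed from Poisson-CDF identities
  (`E[L] = c P(K <= c-1) - x P(K <= c-2)` and the matching second
  moment), which are numerically stable for all `c` and `x`.
* Occupancy vectors are dense arrays over states `0..c_states`, with
  `c_states = round(c0 / delta_c)` by default (208 for `c0 = 10.4` kbp
  at 0.05 kbp/division).

## Problem sizes in the test-suite experiments

The recovery experiments run at the canonical study design: cohorts of
356 subjects over ages 0–85 with truth `(kappa, c0, p) =
(0.075, 10.4, 0.35)`; ABC with 10^6 draws; simulator validation with
1000 replicates of 100 cells and 7 states; snapshots of 5000 cells at
`t* = 2`. Property grids (conservation, moments, limits) run over a few
dozen parameter combinations each. These sizes localise every posterior
and Monte-Carlo comparison well inside the tested tolerances while the
full suite completes in a few minutes on a single core.

## Known limitations

* Senescence is triggered by the *mean* telomere length per cell; the
  shortest-telomere criterion, per-chromosome resolution (184 telomeres)
  and telomerase re-elongation are out of scope.
* `t_star` and `p` are not separately identifiable from a single
  snapshot (see above); only their composite `lambda` and `c0` are.
* Cohort-scale estimates are conditional on the chosen reference scale
  for `delta_c`; only composites are portable between studies.
* The two-phase model's bootstrap profiles `tT` on a grid restricted to
  ±10 years of the point estimate for speed; transition-time CIs are
  indicative only.
* Measurement-noise deconvolution assumes the noise SD is known; it is
  not estimated from the data.
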