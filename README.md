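# telodyn

Telomere length dynamics of hematopoietic stem cells, and inference of
their division mode from telomere data.

## The problem

Human hematopoietic stem cells cannot be observed dividing in vivo, but
every division leaves a mark: the mean telomere length of the daughters
drops by a fixed amount Δc (~50 bp), until critically short telomeres
force permanent cycle arrest. The telomere length distribution of a
blood sample is therefore a fossil record of the stem-cell pool's
replication history. `telodyn` is for modellers and biostatisticians who
want to read that record: it implements a compartment model of telomere
attrition, an exact stochastic simulator, synthetic-data generators for
the two common measurement modalities (Flow-FISH cohort means, Q-FISH
per-cell distributions), and the inference machinery to estimate
division-mode parameters from either.

## The model

Cells are grouped by division count; state *i* has mean telomere length
`c0 − i·Δc`, and state `c = c0/Δc` is absorbing (arrest). Divisions are
*symmetric* (two stem-cell daughters) with probability `p`, else
*asymmetric*. Two regimes:

* **Model 1** (`p = 0`, constant pool `N0`): occupancies follow a
  truncated Poisson wave,
  `N_i(t) = N0 · dpois(i, rt/N0)`, and the mean length decays linearly,
  `E[c](t) ≈ c0 − κt`, with composite loss rate `κ = Δc·r/N0`.
* **Model 2** (`p > 0`, pool grows as `N(t) = N0·t*`,
  `t* = (rp/N0)t + 1`): occupancies follow a generalised Poisson wave,
  `N_i(t) = N0·t*·dpois(i, ρ·ln t*)` with `ρ = (1+p)/p`, and the mean
  decays logarithmically,
  `E[c](t) ≈ c0 − Δc·ρ·ln((κ/Δc)·p·t + 1)` —
  fast in childhood while the pool is small, nearly linear in adults.

A single snapshot of per-cell lengths follows the normalised wave
density with Poisson parameter `λ = ρ·ln t*`, which is what
`fit_distribution()` fits to Q-FISH-like histograms. Inference on
cohort means uses nonlinear least squares, ABC rejection sampling
(uniform priors, R² summary statistic) and AIC/BIC model selection.

## Worked example

Simulate a 356-subject cohort at the canonical truth
(κ = 0.075 kbp/yr, c0 = 10.4 kbp, p = 0.35), fit both models, and
compare them:

```r
library(telodyn)

truth  <- population_scale_params(kappa = 0.075, c0 = 10.4, p = 0.35)
cohort <- generate_population(truth, n_subjects = 356, seed = 7)
fit    <- fit_mean_model(cohort, model = 2, n_boot = 500, seed = 1)
fit
#> Mean telomere length fit (model2): n = 356, k = 4
#>   kappa    0.07479  [0.06139, 0.09119]
#>   c0       10.408  [10.1, 10.71]
#>   p        0.2887  [0.1246, 0.4904]
#>   RSS = 180.1, R^2 = 0.7480, logL = -383.83, AIC = 775.7, BIC = 791.2

model_select(list(fit_mean_model(cohort, model = 1, n_boot = 0), fit))
#> Model selection by AIC (best first):
#>   model k      logL      aic      bic delta_aic rel_likelihood akaike_weight
#>  model2 4 -383.8287 775.6573 791.1571   0.00000       1.000000      0.999000
#>  model1 3 -392.0252 790.0505 801.6753  14.39313       0.000749      0.000749
```

All three generating parameters sit inside their bootstrap 95% CIs, and
the logarithmic model is strongly preferred over the linear one (Akaike
weight 0.999) — the linear fit cannot reproduce the steep telomere loss
in young children. The fitted parameters imply an adult
(ages 20–85) loss rate of `47 bp/year` via `loss_rate()`; at ~50 bp per
division that is about one stem-cell replication per year
(`divisions_per_year(47)`).

A single Q-FISH-like snapshot of 5000 cells at age 40 (truth
`t* = 2, p = 0.02, c0 = 10`, so `λ = ρ·ln t* ≈ 35.35`):

```r
pp   <- stem_cell_params(N0 = 100, r = 125, p = 0.02, c0 = 10, delta_c = 0.05)
snap <- generate_individual(pp, age = 40, n_cells = 5000, cell_noise_sd = 0, seed = 1)
fit_distribution(snap, n_boot = 0)
#> Telomere distribution fit: I0001 (granulocyte, age 40, 5000 cells)
#>   t_star  1.0035
#>   p       0.0001
#>   c0      9.9813
#>   lambda  35.065
#>   derived r/N0 = 0.8781 /year, loss rate = 43.8 bp/year, R^2 = 0.9983
#>   note: (t_star, p) lie on a flat ridge (lambda identifiable only)
```

The identifiable wave parameters are recovered to better than 1%
(λ = 35.07 vs 35.35; c0 = 9.98 vs 10). A single snapshot cannot separate
`t_star` from `p` — only their composite λ — so those two are reported
at a documented ridge convention and flagged; the derived loss rate
(43.8 bp/year here) is stable under that convention.

A YAML-configurable pipeline (`run_pipeline()`, with a thin CLI wrapper
in `inst/scripts/telodyn-cli.R`) chains generation → fitting →
selection and writes seed- and hash-stamped JSON/CSV artifacts.

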