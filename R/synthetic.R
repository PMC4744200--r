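# Synthetic data generators emulating the two measurement modalities:
# cohort tables of mean telomere length per subject (Flow-FISH-like) and
# per-cell telomere length samples for single individuals (Q-FISH-like).

CELL_TYPES <- c("lymphocyte", "granulocyte", "bone_marrow")

#' Generate a synthetic cohort of mean telomere lengths
#'
#' Emulates a Flow-FISH cohort: each subject gets an age, an individual
#' baseline telomere length `c0_i ~ Normal(c0, baseline_sd)` (the newborn
#' variability a single population-level curve ignores), and a measured mean
#' `mean_tl = model-2 curve(age; kappa, c0_i, p) + Normal(0, s)` where the
#' total noise combines measurement noise with (optionally) the process
#' SD of the division process,
#' `s^2 = noise_sd^2 + process_delta_c * kappa * age`,
#' so the cohort SD grows like the square root of age while arrest is
#' negligible. The generating truth is stored as an attribute for
#' recovery studies.
#'
#' @param scale a [population_scale_params()] object (the generating truth).
#' @param n_subjects number of subjects (default 356, a cohort-scale study
#'   spanning ages 0-85).
#' @param age_range ages are drawn uniformly on this interval (years);
#'   default `c(0, 85)`.
#' @param baseline_sd inter-individual baseline SD (kbp, default 0.5).
#' @param noise_sd measurement noise SD (kbp, default 0.3).
#' @param cell_type cell type label for all records (or a vector sampled
#'   per record).
#' @param age_sampling `"uniform"` (default) or `"cohort"`, which places a
#'   cord-blood-like fraction (47/356) of subjects at age 0 and draws the
#'   rest uniformly.
#' @param delta_c reference scale of the cohort curve (kbp, default 1);
#'   see [mean_tl_approx()].
#' @param include_process_sd include the division-process SD term in the
#'   record noise (default `TRUE`); with `FALSE` and both SDs zero every
#'   record lies exactly on the generating curve.
#' @param process_delta_c mechanistic loss per division used for the
#'   process SD term (kbp, default 0.05).
#' @param seed integer RNG seed.
#' @return A `population_sample`: data.frame with columns `subject_id`,
#'   `age_years`, `cell_type`, `mean_tl_kbp`, carrying the truth parameters
#'   in `attr(, "truth")`.
#' @examples
#' sc <- population_scale_params(kappa = 0.075, c0 = 10.4, p = 0.35)
#' pop <- generate_population(sc, n_subjects = 50, seed = 1)
#' head(pop)
#' @export
generate_population <- function(scale, n_subjects = 356,
                                age_range = c(0, 85), baseline_sd = 0.5,
                                noise_sd = 0.3, cell_type = "lymphocyte",
                                age_sampling = c("uniform", "cohort"),
                                delta_c = 1, include_process_sd = TRUE,
                                process_delta_c = 0.05, seed = 1) {
  stopifnot(inherits(scale, "population_scale_params"),
            n_subjects >= 1, baseline_sd >= 0, noise_sd >= 0)
  age_sampling <- match.arg(age_sampling)
  stopifnot(all(cell_type %in% CELL_TYPES))
  set.seed(as.integer(seed))
  ages <- stats::runif(n_subjects, age_range[1], age_range[2])
  if (age_sampling == "cohort") {
    n_cord <- round(n_subjects * 47 / 356)
    ages[seq_len(n_cord)] <- 0
  }
  c0_i <- stats::rnorm(n_subjects, scale$c0, baseline_sd)
  curve <- vapply(seq_len(n_subjects), function(j) {
    sj <- population_scale_params(scale$kappa, max(c0_i[j], 0.1), scale$p)
    mean_tl_approx(sj, ages[j], model = 2, delta_c = delta_c)
  }, numeric(1))
  proc_var <- if (include_process_sd) process_delta_c * scale$kappa * ages
              else 0
  s <- sqrt(noise_sd^2 + proc_var)
  mean_tl <- pmax(curve + stats::rnorm(n_subjects, 0, s), 0.05)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_subjects)),
    age_years = ages,
    cell_type = rep_len(cell_type, n_subjects),
    mean_tl_kbp = mean_tl,
    stringsAsFactors = FALSE)
  structure(out,
            truth = list(kappa = scale$kappa, c0 = scale$c0, p = scale$p,
                         baseline_sd = baseline_sd, noise_sd = noise_sd,
                         delta_c = delta_c,
                         include_process_sd = include_process_sd,
                         process_delta_c = process_delta_c,
                         seed = as.integer(seed)),
            class = c("population_sample", "data.frame"))
}

#' Generate per-cell telomere lengths for one individual
#'
#' Emulates a Q-FISH single-snapshot sample: per-cell division counts are
#' drawn `k ~ Poisson(rho * ln t*)` truncated at `c_states`, telomere
#' lengths are `c0 - k * delta_c` plus Gaussian cell-level measurement
#' noise, floored at zero. An optional per-spot mode averages `n_spots`
#' log-normal telomere spot signals per cell instead of adding Gaussian
#' cell noise.
#'
#' @param params a [stem_cell_params()] object (the generating truth).
#' @param age age of the individual in years.
#' @param n_cells number of cells measured (>= 1).
#' @param cell_noise_sd cell-level measurement noise SD (kbp, default 1.0).
#' @param seed integer RNG seed.
#' @param cell_type cell type label (one of lymphocyte, granulocyte,
#'   bone_marrow).
#' @param subject_id subject identifier string.
#' @param per_spot if `TRUE`, emulate spot-level noise: each cell's length
#'   is the mean of `n_spots` log-normal spot signals (sdlog `spot_sdlog`)
#'   centred on the cell's true length. Off by default.
#' @param n_spots telomere spots per cell (default 184).
#' @param spot_sdlog log-SD of a single spot signal (default 0.5).
#' @return An `individual_sample`: list with `subject_id`, `age`,
#'   `cell_type`, `cell_tl` (kbp vector) and the generating truth.
#' @examples
#' pp <- stem_cell_params(N0 = 100, r = 125, p = 0.02, c0 = 10, delta_c = 0.05)
#' ind <- generate_individual(pp, age = 40, n_cells = 200, seed = 1)
#' mean(ind$cell_tl)
#' @export
generate_individual <- function(params, age, n_cells, cell_noise_sd = 1.0,
                                seed = 1, cell_type = "granulocyte",
                                subject_id = "I0001", per_spot = FALSE,
                                n_spots = 184, spot_sdlog = 0.5) {
  stopifnot(inherits(params, "stem_cell_params"), n_cells >= 1,
            age >= 0, cell_noise_sd >= 0, cell_type %in% CELL_TYPES)
  set.seed(as.integer(seed))
  p <- params$p
  lam <- if (p < .P_EPS) params$r * age / params$N0 else
    (1 + p) / p * log1p(params$r * p * age / params$N0)
  k <- pmin(stats::rpois(n_cells, lam), params$c_states)
  true_tl <- params$c0 - k * params$delta_c
  tl <- if (per_spot) {
    vapply(true_tl, function(m) {
      mu <- log(max(m, 1e-6)) - spot_sdlog^2 / 2
      mean(stats::rlnorm(n_spots, mu, spot_sdlog))
    }, numeric(1))
  } else {
    true_tl + stats::rnorm(n_cells, 0, cell_noise_sd)
  }
  structure(list(subject_id = subject_id, age = age, cell_type = cell_type,
                 cell_tl = pmax(tl, 0),
                 truth = list(t_star = t_star(params, age),
                              p = p, c0 = params$c0,
                              lambda = lam, delta_c = params$delta_c,
                              cell_noise_sd = cell_noise_sd,
                              seed = as.integer(seed))),
            class = "individual_sample")
}

#' @export
print.individual_sample <- function(x, ...) {
  cat(sprintf(
    "Individual sample %s: %s, age %g, %d cells, mean TL %.2f kbp\n",
    x$subject_id, x$cell_type, x$age, length(x$cell_tl), mean(x$cell_tl)))
  invisible(x)
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("Population sample: %d records, ages %.1f-%.1f years\n",
              nrow(x), min(x$age_years), max(x$age_years)))
  print(table(x$cell_type))
  NextMethod()
}
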