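# Cohort-scale fitting: R^2 statistic, least-squares fits of the mean
# telomere length decay (linear, logarithmic, two-phase) with Gaussian
# likelihood bookkeeping for AIC/BIC model selection.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`, the statistic
#' used both for reporting goodness of fit and as the ABC acceptance
#' summary. Always `<= 1`; equals 1 iff predictions match observations
#' exactly, 0 for the constant mean predictor, and can be arbitrarily
#' negative for predictions worse than the mean.
#'
#' @param predicted model predictions.
#' @param observed observed values (same length, >= 2, not all equal).
#' @return R-squared value.
#' @examples
#' r_squared(c(1, 2, 4), c(1, 2, 3))  # 0.5
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2)
    stop("predicted and observed must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are all equal; R^2 undefined")
  1 - sum((predicted - observed)^2) / sst
}

gaussian_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Relative likelihood from a pair of AIC values
#'
#' `exp((aic_ref - aic) / 2)`: the likelihood of the model with `aic`
#' relative to the reference (usually AIC-minimising) model.
#'
#' @param aic AIC of the model under assessment.
#' @param aic_ref AIC of the reference model.
#' @return Relative likelihood (1 when the AICs are equal).
#' @examples
#' relative_likelihood(2550, 2328)  # ~ 1e-48
#' relative_likelihood(2361, 2328)  # ~ 7e-8
#' @export
relative_likelihood <- function(aic, aic_ref) exp((aic_ref - aic) / 2)

new_mean_fit <- function(model, estimates, ci, rss, n, k, delta_c,
                         data_id, boot = NULL, extra = list()) {
  logL <- gaussian_loglik(rss, n)
  structure(c(list(model = model, estimates = estimates, ci = ci,
                   rss = rss, r2 = extra$r2, n = n, k = k, logL = logL,
                   aic = 2 * k - 2 * logL, bic = k * log(n) - 2 * logL,
                   delta_c = delta_c, data_id = data_id, boot = boot),
              extra[setdiff(names(extra), "r2")]),
            class = "mean_fit")
}

#' @export
print.mean_fit <- function(x, ...) {
  cat(sprintf("Mean telomere length fit (%s): n = %d, k = %d\n",
              x$model, x$n, x$k))
  est <- x$estimates
  for (nm in names(est)) {
    ci <- if (!is.null(x$ci) && nm %in% rownames(x$ci))
      sprintf("  [%.4g, %.4g]", x$ci[nm, 1], x$ci[nm, 2]) else ""
    cat(sprintf("  %-8s %.5g%s\n", nm, est[[nm]], ci))
  }
  cat(sprintf("  RSS = %.4g, R^2 = %.4f, logL = %.2f, AIC = %.1f, BIC = %.1f\n",
              x$rss, x$r2, x$logL, x$aic, x$bic))
  invisible(x)
}

data_fingerprint <- function(sample) {
  list(n = nrow(sample),
       sum_age = sum(sample$age_years), sum_tl = sum(sample$mean_tl_kbp))
}

check_population_sample <- function(sample) {
  if (!is.data.frame(sample) ||
      !all(c("age_years", "mean_tl_kbp") %in% names(sample)))
    stop("expected a population sample with columns age_years, mean_tl_kbp")
  if (nrow(sample) < 5 || diff(range(sample$age_years)) <= 1)
    stop("need at least 5 records spanning more than 1 year of ages")
  invisible(sample)
}

# model-2 curve in composite parameters; th = c(kappa, c0, p)
m2_curve <- function(th, t, delta_c) {
  if (th[3] < .P_EPS) th[2] - th[1] * t
  else th[2] - delta_c * (1 + th[3]) / th[3] * log1p(th[1] / delta_c * th[3] * t)
}

fit_model2_ls <- function(age, tl, delta_c, n_starts = 5,
                          lower = c(0, 7, 1e-4), upper = c(0.2, 15, 1)) {
  resid_fn <- function(th) m2_curve(th, age, delta_c) - tl
  qs <- seq(0.1, 0.9, length.out = n_starts)
  lin <- stats::coef(stats::lm(tl ~ age))
  k0 <- min(max(-lin[2], lower[1] + 1e-4), upper[1])
  c00 <- min(max(lin[1], lower[2]), upper[2])
  fits <- lapply(qs, function(q) {
    start <- c(k0, c00, lower[3] + q * (upper[3] - lower[3]))
    f <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    list(par = unname(f$par), value = sum(f$fvec^2))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  # best RSS; ties broken by lowest p to avoid the p ~ 0 boundary trap
  best <- which(vals <= min(vals) + 1e-12 * max(1, min(vals)))
  best <- best[which.min(vapply(fits[best], function(f) f$par[3], numeric(1)))]
  fits[[best]]
}

#' Fit the mean telomere length decay to a cohort
#'
#' Least-squares fit of the population-level mean telomere length curve:
#' model 1 is the linear decay `c0 - kappa * t` (fitted by exact linear
#' algebra); model 2 is the logarithmic decay
#' `c0 - delta_c * ((1+p)/p) * ln((kappa/delta_c) p t + 1)`, fitted by
#' bounded multi-start optimisation. The Gaussian log-likelihood computed
#' from the RSS counts the noise variance as a parameter, giving `k = 3`
#' (model 1) or `k = 4` (model 2) for AIC/BIC. Confidence intervals are
#' nonparametric bootstrap percentiles over resampled records.
#'
#' @param sample a `population_sample` (or any data.frame with columns
#'   `age_years`, `mean_tl_kbp`); >= 5 records spanning > 1 year.
#' @param model 1 or 2.
#' @param delta_c reference scale of the model-2 curve (kbp, default 1);
#'   see [mean_tl_approx()].
#' @param n_boot bootstrap resamples for the CIs (default 1000; 0 skips).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return A `mean_fit` object with estimates, CIs, RSS, R^2, logL,
#'   AIC and BIC.
#' @examples
#' sc <- population_scale_params(kappa = 0.075, c0 = 10.4, p = 0.35)
#' pop <- generate_population(sc, n_subjects = 120, seed = 7)
#' fit_mean_model(pop, model = 2, n_boot = 50)
#' @export
fit_mean_model <- function(sample, model = 2, delta_c = 1,
                           n_boot = 1000, seed = 1, conf = 0.95) {
  check_population_sample(sample)
  model <- match_model(model)
  age <- sample$age_years; tl <- sample$mean_tl_kbp
  alpha <- (1 - conf) / 2

  point <- function(age, tl) {
    if (model == 1L) {
      co <- stats::coef(stats::lm(tl ~ age))
      c(kappa = unname(-co[2]), c0 = unname(co[1]))
    } else {
      fit <- fit_model2_ls(age, tl, delta_c)
      c(kappa = fit$par[1], c0 = fit$par[2], p = fit$par[3])
    }
  }
  est <- point(age, tl)
  pred <- if (model == 1L) est["c0"] - est["kappa"] * age
          else m2_curve(est[c("kappa", "c0", "p")], age, delta_c)
  rss <- sum((pred - tl)^2)
  r2 <- r_squared(pred, tl)

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boot <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(age), replace = TRUE)
      point(age[idx], tl[idx])
    }, est))
    ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
    colnames(ci) <- c("lower", "upper")
  }
  new_mean_fit(model = if (model == 1L) "model1" else "model2",
               estimates = est, ci = ci, rss = rss, n = length(age),
               k = length(est) + 1L, delta_c = delta_c,
               data_id = data_fingerprint(sample), boot = boot,
               extra = list(r2 = r2, conf = conf, seed = as.integer(seed)))
}

two_phase_curve <- function(th, t, delta_c) {
  # th = (kappa1, c01, p1, kappa2, c02, p2, tT); phase 2 restarts at tT
  ifelse(t <= th[7],
         m2_curve(th[1:3], t, delta_c),
         m2_curve(th[4:6], pmax(t - th[7], 0), delta_c))
}

#' Fit a two-phase mean telomere length model
#'
#' Piecewise model with independent composite parameter sets
#' `(kappa, c0, p)` before and after a transition age `tT`; phase 2 is
#' evaluated with its own initial length and its time origin at `tT`
#' (continuity is not enforced). `tT` is profiled over a grid; at each
#' candidate both phases are fitted independently by least squares and the
#' total RSS is minimised. Structural parameters: 7, plus the Gaussian
#' sigma (`k = 8`). Candidates leaving fewer than 3 records in either phase
#' are rejected; a candidate at or beyond the maximum age degenerates to
#' the single-phase model-2 fit.
#'
#' @inheritParams fit_mean_model
#' @param tT_grid candidate transition ages (years); default an annual grid
#'   over the intersection of the observed age range and `[0, 80]`.
#' @param n_boot bootstrap resamples for CIs (default 200; the profile
#'   refit is costlier than the single-phase fits).
#' @return A `mean_fit` object (`model = "two_phase"`) whose estimates are
#'   `kappa1, c01, p1, kappa2, c02, p2, tT`.
#' @export
fit_two_phase <- function(sample, delta_c = 1, tT_grid = NULL,
                          n_boot = 200, seed = 1, conf = 0.95) {
  check_population_sample(sample)
  age <- sample$age_years; tl <- sample$mean_tl_kbp
  if (is.null(tT_grid))
    tT_grid <- seq(max(0, floor(min(age)) + 1),
                   min(80, ceiling(max(age))), by = 1)

  profile_fit <- function(age, tl, grid) {
    best <- NULL
    for (tT in grid) {
      in1 <- age <= tT; in2 <- !in1
      if (sum(in2) == 0 || tT >= max(age)) {
        f <- fit_model2_ls(age, tl, delta_c)
        cand <- list(par = c(f$par, f$par, tT), rss = f$value, degenerate = TRUE)
      } else {
        if (sum(in1) < 3 || sum(in2) < 3) next
        f1 <- fit_model2_ls(age[in1], tl[in1], delta_c)
        f2 <- fit_model2_ls(age[in2] - tT, tl[in2], delta_c)
        cand <- list(par = c(f1$par, f2$par, tT), rss = f1$value + f2$value,
                     degenerate = FALSE)
      }
      if (is.null(best) || cand$rss < best$rss) best <- cand
    }
    if (is.null(best)) stop("no admissible transition age in tT_grid")
    best
  }

  best <- profile_fit(age, tl, tT_grid)
  nm <- c("kappa1", "c01", "p1", "kappa2", "c02", "p2", "tT")
  est <- stats::setNames(best$par, nm)
  pred <- two_phase_curve(best$par, age, delta_c)
  rss <- sum((pred - tl)^2)
  r2 <- r_squared(pred, tl)

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    # bootstrap profiles tT on a coarser grid around the point estimate
    bgrid <- tT_grid[abs(tT_grid - best$par[7]) <= 10]
    boot <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(age), replace = TRUE)
      out <- try(profile_fit(age[idx], tl[idx], bgrid)$par, silent = TRUE)
      if (inherits(out, "try-error")) rep(NA_real_, 7) else out
    }, numeric(7)))
    colnames(boot) <- nm
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 2, stats::quantile,
                  probs = c(alpha, 1 - alpha), na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
  }
  new_mean_fit(model = "two_phase", estimates = est, ci = ci, rss = rss,
               n = length(age), k = 8L, delta_c = delta_c,
               data_id = data_fingerprint(sample), boot = boot,
               extra = list(r2 = r2, conf = conf, seed = as.integer(seed),
                            degenerate = best$degenerate))
}

#' Rank fitted models by AIC (and BIC)
#'
#' Given two or more [fit_mean_model()] / [fit_two_phase()] results on the
#' same data, computes Akaike differences, relative likelihoods
#' `exp((AIC_min - AIC_i)/2)`, Akaike weights and the BIC ranking.
#'
#' @param fits a list of `mean_fit` objects fitted to the same sample.
#' @return A `model_selection` object: data.frame with one row per model,
#'   ordered by AIC.
#' @export
model_select <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "mean_fit")))
  ids <- lapply(fits, `[[`, "data_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("fits were computed on different datasets")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$rel_likelihood <- relative_likelihood(tab$aic, min(tab$aic))
  tab$akaike_weight <- tab$rel_likelihood / sum(tab$rel_likelihood)
  tab$bic_rank <- rank(tab$bic)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  structure(tab, class = c("model_selection", "data.frame"))
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AIC (best first):\n")
  y <- as.data.frame(x)
  y$rel_likelihood <- signif(y$rel_likelihood, 3)
  y$akaike_weight <- signif(y$akaike_weight, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
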