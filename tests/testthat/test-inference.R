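# Inference layer: R^2, mean-curve fits, ABC rejection, model selection,
# distribution fits and loss-rate trends.

test_that("R^2 has its textbook values and guards", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_lte(r_squared(c(9, 1, 5), obs), 1)
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_error(r_squared(c(1, 2), c(3, 3)), "all equal")
})

test_that("relative likelihood follows the AIC difference identity", {
  expect_equal(relative_likelihood(100, 100), 1)
  expect_equal(relative_likelihood(2550, 2328), exp(-111))
  expect_equal(relative_likelihood(2361, 2328), exp(-16.5))
})

test_that("noiseless cohorts are recovered exactly by least squares", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 120, baseline_sd = 0,
                             noise_sd = 0, include_process_sd = FALSE,
                             seed = 9)
  f <- fit_mean_model(pop, model = 2, n_boot = 0)
  expect_equal(unname(f$estimates), c(0.075, 10.4, 0.35), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("AIC/BIC bookkeeping matches the Gaussian likelihood convention", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 80, seed = 4)
  f1 <- fit_mean_model(pop, model = 1, n_boot = 0)
  f2 <- fit_mean_model(pop, model = 2, n_boot = 0)
  expect_equal(f1$k, 3)  # kappa, c0, sigma
  expect_equal(f2$k, 4)  # kappa, c0, p, sigma
  n <- f2$n
  expect_equal(f2$logL, -n / 2 * (log(2 * pi * f2$rss / n) + 1))
  expect_equal(f2$aic, 2 * f2$k - 2 * f2$logL)
  expect_equal(f2$bic, f2$k * log(n) - 2 * f2$logL)
})

test_that("a linear fit to growing-pool data underestimates the newborn length", {
  sc <- cohort_truth()
  underestimates <- vapply(1:6, function(s) {
    pop <- generate_population(sc, n_subjects = 356, seed = s)
    fit_mean_model(pop, model = 1, n_boot = 0)$estimates[["c0"]] < 10.4
  }, logical(1))
  expect_true(all(underestimates))
})

test_that("default-noise cohort estimates cover the truth (bootstrap CIs)", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 356, seed = 1)
  f <- fit_mean_model(pop, model = 2, n_boot = 400, seed = 1)
  expect_true(f$ci["kappa", 1] <= 0.075 && 0.075 <= f$ci["kappa", 2])
  expect_true(f$ci["c0", 1] <= 10.4 && 10.4 <= f$ci["c0", 2])
  expect_true(f$ci["p", 1] <= 0.35 && 0.35 <= f$ci["p", 2])
})

test_that("two-phase fit degenerates to single-phase at the maximum age", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 120, seed = 5)
  f2 <- fit_mean_model(pop, model = 2, n_boot = 0)
  ftp <- fit_two_phase(pop, tT_grid = max(pop$age_years) + 1, n_boot = 0)
  expect_true(ftp$degenerate)
  expect_equal(unname(ftp$estimates[c("kappa1", "c01", "p1")]),
               unname(f2$estimates), tolerance = 1e-8)
  expect_equal(ftp$k, 8)
})

test_that("two-phase fit recovers a transition at age 7 within 2 years", {
  sc1 <- population_scale_params(kappa = 0.15, c0 = 10.4, p = 0.6)
  sc2 <- population_scale_params(kappa = 0.05, c0 = 9.0, p = 0.05)
  set.seed(21)
  # transition studies need dense sampling around childhood ages
  ages <- c(runif(150, 0, 15), runif(150, 0, 85))
  tl <- ifelse(ages <= 7, mean_tl_approx(sc1, ages, 2),
               mean_tl_approx(sc2, pmax(ages - 7, 0), 2)) +
    rnorm(300, 0, 0.2)
  pop <- data.frame(subject_id = sprintf("S%03d", 1:300), age_years = ages,
                    cell_type = "lymphocyte", mean_tl_kbp = tl)
  ftp <- fit_two_phase(pop, n_boot = 0)
  expect_lte(abs(ftp$estimates[["tT"]] - 7), 2)
})

test_that("model selection requires comparable fits and orders by AIC", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 200, seed = 8)
  f1 <- fit_mean_model(pop, model = 1, n_boot = 0)
  f2 <- fit_mean_model(pop, model = 2, n_boot = 0)
  ms <- model_select(list(f1, f2))
  expect_s3_class(ms, "model_selection")
  expect_equal(ms$model[1], "model2")
  expect_equal(ms$rel_likelihood[1], 1)
  expect_equal(ms$rel_likelihood[2],
               relative_likelihood(ms$aic[2], ms$aic[1]))
  expect_equal(sum(ms$akaike_weight), 1)
  other <- generate_population(sc, n_subjects = 150, seed = 9)
  f_other <- fit_mean_model(other, model = 1, n_boot = 0)
  expect_error(model_select(list(f2, f_other)), "different datasets")
})

test_that("ABC with an accept-everything rule returns the prior", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 80, seed = 2)
  ab <- abc_rejection(pop, model = 2, n_draws = 4000,
                      threshold_rule = list(type = "absolute",
                                            cutoff = -Inf), seed = 5)
  expect_equal(ab$n_accepted, 4000)
  pr <- prior_spec()
  expect_gt(ks.test(ab$accepted[, "kappa"],
                    "punif", pr$kappa[1], pr$kappa[2])$p.value, 0.01)
  expect_gt(ks.test(ab$accepted[, "c0"],
                    "punif", pr$c0[1], pr$c0[2])$p.value, 0.01)
  expect_gt(ks.test(ab$accepted[, "p"],
                    "punif", pr$p[1], pr$p[2])$p.value, 0.01)
})

test_that("ABC acceptance respects the threshold and the prior box", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 200, seed = 3)
  ab <- abc_rejection(pop, model = 2, n_draws = 50000, seed = 6)
  expect_true(all(ab$r2 >= ab$threshold))
  expect_gte(ab$r2_max, ab$threshold)
  pr <- prior_spec()
  expect_true(all(ab$accepted[, "kappa"] >= pr$kappa[1] &
                    ab$accepted[, "kappa"] <= pr$kappa[2]))
  expect_true(all(ab$accepted[, "p"] >= pr$p[1] &
                    ab$accepted[, "p"] <= pr$p[2]))
  # reproducibility
  ab2 <- abc_rejection(pop, model = 2, n_draws = 50000, seed = 6)
  expect_identical(ab$accepted, ab2$accepted)
  expect_error(abc_rejection(pop, model = 2, n_draws = 5000,
                             threshold_rule = list(type = "absolute",
                                                   cutoff = 0.9999),
                             seed = 1),
               "zero acceptances")
})

test_that("ABC posterior mode agrees with the least-squares fit", {
  sc <- cohort_truth()
  pop <- generate_population(sc, n_subjects = 356, seed = 1)
  f <- fit_mean_model(pop, model = 2, n_boot = 400, seed = 1)
  ab <- abc_rejection(pop, model = 2, n_draws = 1e5, seed = 2)
  for (nm in c("kappa", "c0", "p"))
    expect_true(ab$posterior[nm, "mode"] >= f$ci[nm, 1] &&
                  ab$posterior[nm, "mode"] <= f$ci[nm, 2])
})

test_that("distribution fit recovers the identifiable wave parameters", {
  pp <- individual_truth()
  ind <- generate_individual(pp, 40, 5000, cell_noise_sd = 0, seed = 1)
  fd <- fit_distribution(ind, n_boot = 0)
  expect_lt(abs(fd$estimates[["lambda"]] - ind$truth$lambda) /
              ind$truth$lambda, 0.05)
  expect_lt(abs(fd$estimates[["c0"]] - 10) / 10, 0.05)
  expect_true(fd$degenerate)
  expect_gte(fd$estimates[["t_star"]], 1)
  # the derived loss rate approaches its ridge-stable limit
  expect_equal(fd$loss_rate_bp_per_year,
               1000 * 0.05 * fd$estimates[["lambda"]] / 40,
               tolerance = 0.02)
  expect_error(fit_distribution(
    generate_individual(pp, 40, 40, seed = 1)), "at least 50 cells")
})

test_that("bias of the distribution fit shrinks with the cell count", {
  pp <- individual_truth()
  errs <- vapply(c(500, 5000), function(n) {
    e <- vapply(1:5, function(s) {
      ind <- generate_individual(pp, 40, n, cell_noise_sd = 0, seed = s)
      fd <- fit_distribution(ind, n_boot = 0)
      abs(fd$estimates[["lambda"]] - ind$truth$lambda)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.3)
  lam_true <- (1.02 / 0.02) * log(2)
  expect_lt(errs[2] / lam_true, 0.05)
})

test_that("derived snapshot quantities follow their plug-through formulas", {
  dr <- telodyn:::derive_rates(t_star = 2, p = 0.02, age = 40,
                               delta_c = 0.05)
  expect_equal(dr$r_over_N0, 1.25)
  expect_equal(dr$loss_rate_bp_per_year, 31.875)
  expect_equal(dr$loss_rate_bp_per_year, 31.9, tolerance = 1e-2)
})

test_that("cohort loss-rate trends detect the sign of age effects", {
  fake_fit <- function(age, rate, type = "granulocyte")
    structure(list(cell_type = type, age = age,
                   loss_rate_bp_per_year = rate), class = "dist_fit")
  flat <- lapply(c(20, 40, 60, 80), fake_fit, rate = 50)
  tr <- cohort_loss_rate_trend(flat)
  expect_equal(tr$slope, 0)
  set.seed(2)
  up <- lapply(seq(20, 80, by = 5),
               function(a) fake_fit(a, 30 + 0.5 * a + rnorm(1, 0, 2),
                                    "lymphocyte"))
  down <- lapply(seq(20, 80, by = 5),
                 function(a) fake_fit(a, 90 - 0.7 * a + rnorm(1, 0, 2)))
  tu <- cohort_loss_rate_trend(up)
  td <- cohort_loss_rate_trend(down)
  expect_gt(tu$slope, 0); expect_gt(tu$lower, 0)
  expect_lt(td$slope, 0); expect_lt(td$upper, 0)
  expect_error(cohort_loss_rate_trend(flat[1:2]), "at least 3")
})
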