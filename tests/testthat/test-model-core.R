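# Closed-form machinery: occupancy distributions, moments, MGF, wave
# maxima, loss rates.

test_that("parameter constructors enforce the c0 = c_states * delta_c convention", {
  pp <- stem_cell_params(N0 = 100, r = 100, p = 0.3, c0 = 10.4, delta_c = 0.05)
  expect_identical(pp$c_states, 208L)
  expect_equal(pp$c0, 10.4)
  expect_error(stem_cell_params(100, 100, 0.3, c_states = 100, c0 = 10.4),
               "c_states")
  expect_error(stem_cell_params(100, -1, 0.3, c0 = 10), "r")
  expect_error(stem_cell_params(100, 100, 1.3, c0 = 10), "p")
  expect_error(population_scale_params(-0.1, 10, 0.3), "kappa")
  sc <- as_population_scale(pp)
  expect_equal(sc$kappa, 0.05 * 100 / 100)
})

test_that("state_length maps indices linearly and pins arrest at zero", {
  pp <- stem_cell_params(100, 100, 0, c0 = 10, delta_c = 0.05)
  expect_equal(state_length(pp, 0), 10)
  expect_equal(state_length(pp, 200), 0)
  pp2 <- stem_cell_params(100, 100, 0, c0 = 10.4, delta_c = 0.05)
  expect_equal(state_length(pp2, 40), 8.4)
  expect_error(state_length(pp, 201), "out of range")
  expect_error(state_length(pp, -1), "out of range")
})

test_that("model-1 occupancy matches the truncated Poisson solution", {
  pp <- demo_params()
  o0 <- occupancy_model1(pp, 0)
  expect_equal(o0$counts, c(100, rep(0, 7)))
  o7 <- occupancy_model1(pp, 7)
  expect_equal(o7$counts[4], 5.212925, tolerance = 1e-6)       # state 3
  expect_equal(o7$counts[8], 55.02889, tolerance = 1e-6)       # arrest
  expect_error(occupancy_model1(pp, -1), ">= 0")
})

test_that("model-1 conservation holds across a time grid", {
  pp <- stem_cell_params(100, 80, 0, c0 = 10, delta_c = 0.05)
  for (t in c(0, 0.5, 2, 10, 50, 200, 1000))
    expect_equal(sum(occupancy_model1(pp, t)$counts), 100,
                 tolerance = 1e-10)
})

test_that("model-2 occupancy grows as N0 * t_star and reduces to model 1", {
  pp <- stem_cell_params(100, 100, 0.3, c_states = 60, delta_c = 0.05)
  t_e <- (exp(1) - 1) * 100 / (100 * 0.3)   # chosen so t* = e
  o <- occupancy_model2(pp, t_e)
  expect_equal(sum(o$counts), 100 * exp(1), tolerance = 1e-8)
  expect_equal(o$total, 100 * exp(1), tolerance = 1e-8)
  # growth law on a (t, p) grid
  for (p in c(0.05, 0.3, 0.8)) for (t in c(0.1, 1, 5, 20)) {
    ppg <- stem_cell_params(100, 100, p, c_states = 400, delta_c = 0.05)
    expect_equal(sum(occupancy_model2(ppg, t)$counts),
                 100 * t_star(ppg, t), tolerance = 1e-8)
  }
  # t = 0 initial condition
  o0 <- occupancy_model2(pp, 0)
  expect_equal(o0$counts, c(100, rep(0, 60)))
  # p -> 0 limit: per-state relative agreement
  pl <- stem_cell_params(100, 100, 1e-8, c_states = 7, delta_c = 0.05)
  p0 <- stem_cell_params(100, 100, 0, c_states = 7, delta_c = 0.05)
  c1 <- occupancy_model2(pl, 3)$counts
  c2 <- occupancy_model1(p0, 3)$counts
  expect_lt(max(abs(c1 - c2) / pmax(c2, 1e-12)), 1e-4)
})

test_that("exact mean matches the brute-force moment and its known limits", {
  pp <- stem_cell_params(100, 100, 0, c0 = 10, delta_c = 0.05)
  expect_equal(mean_tl_exact(pp, 0, 1), 10)
  expect_equal(mean_tl_exact(pp, 20, 1), 9.0, tolerance = 1e-6)
  expect_lt(mean_tl_exact(pp, 1e5, 1), 1e-6)  # asymptotic exhaustion
  for (t in c(0.5, 5, 50, 150, 250, 400))
    expect_equal(mean_tl_exact(pp, t, 1), brute_mean_tl(pp, t, 1),
                 tolerance = 1e-8)
  pp2 <- stem_cell_params(100, 100, 0.3, c0 = 10, delta_c = 0.05)
  for (t in c(0.5, 5, 50, 150))
    expect_equal(mean_tl_exact(pp2, t, 2), brute_mean_tl(pp2, t, 2),
                 tolerance = 1e-8)
  # non-increasing in t, both models
  ts <- seq(0, 300, by = 10)
  expect_true(all(diff(mean_tl_exact(pp, ts, 1)) <= 1e-12))
  expect_true(all(diff(mean_tl_exact(pp2, ts, 2)) <= 1e-12))
})

test_that("approximate mean reproduces worked values and the p -> 0 limit", {
  expect_equal(mean_tl_approx(population_scale_params(0.05, 10, 0),
                              20, model = 1), 9.0)
  sc <- cohort_truth()
  expect_equal(mean_tl_approx(sc, 20, model = 2, delta_c = 0.05),
               10.4 - 0.05 * (1.35 / 0.35) * log(1.5 * 0.35 * 20 + 1),
               tolerance = 1e-12)
  expect_equal(mean_tl_approx(sc, 20, model = 2, delta_c = 0.05), 9.93,
               tolerance = 1e-3)
  sc0 <- population_scale_params(0.05, 10, 1e-10)
  expect_equal(mean_tl_approx(sc0, 30, model = 2),
               mean_tl_approx(sc0, 30, model = 1), tolerance = 1e-6)
})

test_that("variance matches brute force, grows linearly, then collapses", {
  pp <- stem_cell_params(100, 100, 0, c_states = 200, delta_c = 0.05)
  expect_equal(variance_model1(pp, 0), 0)
  expect_equal(variance_model1(pp, 25) / 0.05^2, 25, tolerance = 1e-6)
  for (t in c(1, 25, 120, 200, 300))
    expect_equal(variance_model1(pp, t), brute_var_tl(pp, t, 1),
                 tolerance = 1e-8)
  expect_equal(sd_approx(pp, 25), 0.05 * 5)
  # late times: most cells arrested, variance decreasing towards zero
  expect_lt(variance_model1(pp, 400), variance_model1(pp, 200))
  expect_lt(variance_model1(pp, 2000), 1e-6)
})

test_that("MGF is normalised and its derivatives reproduce the moments", {
  pp <- demo_params()
  expect_equal(mgf_model1(pp, 3, 0), 1)
  for (z in c(-0.5, 0.1, 0.4))
    expect_equal(mgf_model1(pp, 3, z), brute_mgf(pp, 3, z),
                 tolerance = 1e-10)
  # 5-point stencils keep the finite-difference error below the tolerance
  h <- 1e-3
  M <- function(z) mgf_model1(pp, 3, z)
  d1 <- (M(-2 * h) - 8 * M(-h) + 8 * M(h) - M(2 * h)) / (12 * h)
  expect_equal(d1, mean_tl_exact(pp, 3, 1), tolerance = 1e-6)
  d2 <- (-M(2 * h) + 16 * M(h) - 30 * M(0) + 16 * M(-h) - M(-2 * h)) /
    (12 * h^2)
  expect_equal(d2 - d1^2, variance_model1(pp, 3), tolerance = 1e-6)
})

test_that("wave maxima match their closed forms and the grid argmax", {
  pp <- demo_params()
  w <- wave_max(pp, 6, model = 1)
  expect_equal(w$t_max, 6)
  w2 <- stem_cell_params(100, 100, 0, c_states = 8, delta_c = 0.05)
  w7 <- wave_max(w2, 7, model = 1)
  expect_equal(w7$t_max, 7)
  expect_equal(w7$peak_count, 100 * dpois(7, 7), tolerance = 1e-10)
  expect_equal(w7$peak_count, 14.90, tolerance = 1e-3)
  expect_equal(w7$peak_stirling, 100 / sqrt(2 * pi * 7), tolerance = 1e-10)
  pp2 <- stem_cell_params(100, 100, 0.3, c_states = 7, delta_c = 0.05)
  wm2 <- wave_max(pp2, 2, model = 2)
  expect_equal(wm2$t_max, 2.74, tolerance = 1e-2)
  expect_equal(wm2$peak_count, 45.7, tolerance = 1e-2)
  expect_equal(wm2$peak_count, occupancy_model2(pp2, wm2$t_max)$counts[3],
               tolerance = 1e-8)
  expect_error(wave_max(pp, 0, model = 1), "state index")
  expect_error(wave_max(pp, 7, model = 1), "state index")
})

test_that("closed-form t_max agrees with grid argmax for i = 1..20, both models", {
  pp1 <- stem_cell_params(100, 100, 0, c_states = 25, delta_c = 0.05)
  pp2 <- stem_cell_params(100, 100, 0.3, c_states = 25, delta_c = 0.05)
  for (i in 1:20) {
    tm1 <- wave_max(pp1, i, model = 1)$t_max
    g1 <- grid_argmax_t(pp1, i, 1, t_hi = 2 * tm1 + 1)
    expect_lt(abs(tm1 - g1), (2 * tm1 + 1) / 600 + 1e-9)
    tm2 <- wave_max(pp2, i, model = 2)$t_max
    g2 <- grid_argmax_t(pp2, i, 2, t_hi = 2 * tm2 + 1)
    expect_lt(abs(tm2 - g2), (2 * tm2 + 1) / 600 + 1e-9)
  }
})

test_that("snapshot density is normalised with the stated mean and mode", {
  xs <- seq(0, 10, by = 0.005)
  fx <- telomere_density(xs, t_star = 2, p = 0.02, c0 = 10, delta_c = 0.05)
  expect_true(all(fx[xs > 10] == 0))
  expect_equal(sum(fx) * 0.005, 1, tolerance = 1e-6)
  m <- sum(xs * fx) * 0.005
  expect_equal(m, 10 - 0.05 * (1.02 / 0.02) * log(2), tolerance = 1e-3)
  expect_equal(m, 8.232, tolerance = 1e-3)
  # mode near c0 - delta_c * rho * ln t*
  expect_equal(xs[which.max(fx)], 10 - 0.05 * (1.02 / 0.02) * log(2),
               tolerance = 0.05)
  # t_star = 1: all mass in the first division cell at c0
  f1 <- telomere_density(c(9.5, 9.99, 10), t_star = 1, p = 0.1, c0 = 10)
  expect_equal(f1, c(0, 40, 40))
  expect_error(telomere_density(5, t_star = 0.9, p = 0.1, c0 = 10), "t_star")
})

test_that("loss rate derives from the mean decay and falls with age", {
  sc <- cohort_truth()
  expect_equal(loss_rate(sc, 0, delta_c = 0.05), 101.25)
  expect_equal(loss_rate(sc, 0), 101.25)  # t = 0 independent of reference
  # finite differences on the mean curve (default cohort reference)
  h <- 1e-6
  for (t in c(0, 10, 40, 80)) {
    fd <- -(mean_tl_approx(sc, t + h, 2) - mean_tl_approx(sc, max(t - h, 0), 2)) /
      (h + min(t, h)) * 1000
    expect_equal(loss_rate(sc, t), fd, tolerance = 1e-4)
  }
  rates <- loss_rate(sc, seq(0, 80, by = 5))
  expect_true(all(diff(rates) < 0))
  sc0 <- population_scale_params(0.05, 10, 0)
  expect_equal(loss_rate(sc0, c(0, 30, 90)), rep(50, 3))
})

test_that("replication-rate arithmetic converts loss rates to divisions", {
  expect_equal(divisions_per_year(50, delta_c = 0.05), 1)
  expect_equal(divisions_per_year(75, delta_c = 0.05), 1.5)
})
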