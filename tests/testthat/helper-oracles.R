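# Independent brute-force oracles: direct sums over occupancy vectors and
# grid searches, kept free of the closed-form code paths they check.

occupancy_of <- function(params, t, model) {
  if (model == 1) occupancy_model1(params, t) else occupancy_model2(params, t)
}

# first moment of the telomere length over the occupancy vector
# (arrest state contributes length zero)
brute_mean_tl <- function(params, t, model = 1) {
  occ <- occupancy_of(params, t, model)
  lengths <- state_length(params, seq_along(occ$counts) - 1L)
  sum(lengths * occ$counts) / occ$total
}

brute_var_tl <- function(params, t, model = 1) {
  occ <- occupancy_of(params, t, model)
  lengths <- state_length(params, seq_along(occ$counts) - 1L)
  w <- occ$counts / occ$total
  sum(lengths^2 * w) - sum(lengths * w)^2
}

brute_mgf <- function(params, t, z) {
  occ <- occupancy_model1(params, t)
  lengths <- state_length(params, seq_along(occ$counts) - 1L)
  sum(exp(z * lengths) * occ$counts) / occ$total
}

# argmax over a time grid of the occupancy of state i
grid_argmax_t <- function(params, i, model, t_hi, n_grid = 600) {
  ts <- seq(t_hi / n_grid, t_hi, length.out = n_grid)
  counts <- vapply(ts, function(t) occupancy_of(params, t, model)$counts[i + 1L],
                   numeric(1))
  ts[which.max(counts)]
}

# standard synthetic truths used across tests
cohort_truth <- function() population_scale_params(kappa = 0.075,
                                                   c0 = 10.4, p = 0.35)

individual_truth <- function() stem_cell_params(N0 = 100, r = 125, p = 0.02,
                                                c0 = 10, delta_c = 0.05)

demo_params <- function(p = 0) stem_cell_params(N0 = 100, r = 100, p = p,
                                                c_states = 7, delta_c = 0.05)
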