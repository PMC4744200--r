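# Individual-based stochastic simulation of the division/arrest process.
# Cells are book-kept as counts per state; each division removes the mother
# from state i and adds one (asymmetric) or two (symmetric) daughters to
# state i + 1. The arrest state c_states is absorbing.

#' Simulate the stochastic division/arrest process
#'
#' Event-driven simulation of `N0` cells dividing with symmetric probability
#' `p`. With the default timing, every non-arrested cell divides at the
#' per-cell rate `r / (N0 + r p t)` (model 1 with `p = 0`: `r / N0`), the
#' exact stochastic counterpart of the deterministic occupancy equations:
#' the total division rate is `r` times the non-arrested fraction of the
#' expected pool, i.e. effectively the constant population output `r` while
#' arrest is negligible. Waiting times are sampled from the corresponding
#' (inhomogeneous) exponential distribution in closed form.
#' `timing = "constant_output"` instead keeps the total division rate pinned
#' at exactly `r` regardless of pool size, for sensitivity checks of the
#' constant-output idealisation.
#'
#' @param params a [stem_cell_params()] object.
#' @param t_end end time in years (> 0).
#' @param checkpoints times in `[0, t_end]` at which to record occupancies.
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @param timing `"ode_matched"` (default) or `"constant_output"`, see
#'   Details.
#' @return A `trajectory` object: list with `checkpoints`, `occupancies`
#'   (one `state_occupancy` per checkpoint), `population_sizes`, `seed`,
#'   `params`, `timing`.
#' @examples
#' pp <- stem_cell_params(N0 = 100, r = 100, p = 0, c_states = 7, delta_c = 0.05)
#' tr <- simulate_population(pp, t_end = 3, checkpoints = c(1, 2, 3), seed = 1)
#' tr$population_sizes  # constant at 100 for p = 0
#' @export
simulate_population <- function(params, t_end, checkpoints, seed,
                                timing = c("ode_matched", "constant_output")) {
  stopifnot(inherits(params, "stem_cell_params"), t_end > 0)
  timing <- match.arg(timing)
  if (params$c_states < 1) stop("all cells are initially arrested")
  checkpoints <- sort(unique(checkpoints))
  if (any(checkpoints < 0) || any(checkpoints > t_end))
    stop("checkpoints must lie in [0, t_end]")
  set.seed(as.integer(seed))

  cs <- params$c_states
  N0 <- params$N0; r <- params$r; p <- params$p
  counts <- c(N0, numeric(cs))          # states 0..cs
  t_now <- 0
  ck_idx <- 1L
  n_ck <- length(checkpoints)
  occ <- vector("list", n_ck)
  pop <- numeric(n_ck)

  record_until <- function(time_reached) {
    while (ck_idx <= n_ck && checkpoints[ck_idx] <= time_reached) {
      occ[[ck_idx]] <<- new_state_occupancy(
        checkpoints[ck_idx], counts, total = sum(counts),
        model = "simulation", params = params)
      pop[ck_idx] <<- sum(counts)
      ck_idx <<- ck_idx + 1L
    }
  }

  repeat {
    m <- sum(counts[1:cs])              # non-arrested cells
    if (m == 0) { record_until(t_end); break }
    e <- stats::rexp(1)
    if (timing == "constant_output") {
      dt <- e / r
    } else if (p > 0) {
      # per-cell rate r/(N0 + r p t); integrated hazard from t_now over dt:
      # (m/p) * log((N0 + r p (t_now + dt)) / (N0 + r p t_now)) = e
      a <- N0 + r * p * t_now
      dt <- (a * exp(e * p / m) - a) / (r * p)
    } else {
      dt <- e * N0 / (r * m)
    }
    t_next <- t_now + dt
    if (t_next > t_end) { record_until(t_end); break }
    record_until(t_next - .Machine$double.eps * t_next)
    t_now <- t_next
    # choose the mother uniformly among non-arrested cells
    u <- stats::runif(1) * m
    i <- findInterval(u, cumsum(counts[1:cs]), left.open = TRUE) + 1L
    counts[i] <- counts[i] - 1
    n_daughters <- if (stats::runif(1) <= p) 2 else 1
    counts[i + 1L] <- counts[i + 1L] + n_daughters
  }
  record_until(t_end)

  structure(list(checkpoints = checkpoints, occupancies = occ,
                 population_sizes = pop, seed = as.integer(seed),
                 params = params, timing = timing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Stochastic trajectory: %d checkpoints to t = %g years (seed %d)\n",
              length(x$checkpoints), max(x$checkpoints), x$seed))
  cat(sprintf("  population %g -> %g cells\n", x$params$N0,
              x$population_sizes[length(x$population_sizes)]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  do.call(rbind, lapply(x$occupancies, as.data.frame))
}

#' Export a trajectory as long-format CSV
#'
#' Columns `time`, `state`, `length_kbp`, `count`, one row per checkpoint
#' and state.
#'
#' @param trajectory a [simulate_population()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Ensemble-averaged occupancies over independent replicates
#'
#' Runs [simulate_population()] `n_reps` times with replicate seeds derived
#' deterministically from the master seed (`seed`, `seed + 1`, ...) and
#' returns per-state means and standard errors at each checkpoint — the
#' Monte-Carlo estimate the analytic occupancy formulas are validated
#' against.
#'
#' @inheritParams simulate_population
#' @param n_reps number of replicates (>= 2).
#' @param replicate_seeds optional explicit vector of `n_reps` seeds,
#'   overriding the derivation rule.
#' @return List with `checkpoints`, `mean` and `se` (matrices, one row per
#'   checkpoint, one column per state), `n_reps`, `params`.
#' @export
ensemble_mean <- function(params, t_end, checkpoints, n_reps, seed,
                          replicate_seeds = NULL,
                          timing = c("ode_matched", "constant_output")) {
  stopifnot(n_reps >= 2)
  timing <- match.arg(timing)
  checkpoints <- sort(unique(checkpoints))
  if (is.null(replicate_seeds))
    replicate_seeds <- as.integer(seed) + seq_len(n_reps) - 1L
  stopifnot(length(replicate_seeds) == n_reps)
  cs <- params$c_states
  acc <- array(0, dim = c(length(checkpoints), cs + 1L, n_reps))
  for (k in seq_len(n_reps)) {
    tr <- simulate_population(params, t_end, checkpoints,
                              seed = replicate_seeds[k], timing = timing)
    acc[, , k] <- t(vapply(tr$occupancies, function(o) o$counts,
                           numeric(cs + 1L)))
  }
  mu <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), stats::sd) / sqrt(n_reps)
  dimnames(mu) <- dimnames(se) <-
    list(paste0("t=", checkpoints), paste0("state", 0:cs))
  list(checkpoints = checkpoints, mean = mu, se = se,
       n_reps = n_reps, params = params, seeds = replicate_seeds)
}
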