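#' Expected state occupancy under purely asymmetric divisions (model 1)
#'
#' With only asymmetric divisions (`p = 0`) the stem-cell pool is conserved
#' and the expected number of cells that have divided `i` times is the
#' truncated Poisson expression
#' `N_i(t) = N0 * (rt/N0)^i * exp(-rt/N0) / i!` for `i < c_states`; the
#' arrest state collects the remainder so that the total is exactly `N0`.
#'
#' @param params a [stem_cell_params()] object (its `p` is ignored here).
#' @param t time in years (>= 0).
#' @return A `state_occupancy` object: list with `t`, `counts` (vector over
#'   states `0..c_states`), `total`, `model`.
#' @examples
#' pp <- stem_cell_params(N0 = 100, r = 100, p = 0, c_states = 7, delta_c = 0.05)
#' occupancy_model1(pp, t = 7)
#' @export
occupancy_model1 <- function(params, t) {
  stopifnot(inherits(params, "stem_cell_params"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop("t must be a single number >= 0")
  cs <- params$c_states
  x <- params$r * t / params$N0
  counts <- params$N0 * stats::dpois(0:(cs - 1L), x)
  arrest <- params$N0 * stats::ppois(cs - 1L, x, lower.tail = FALSE)
  new_state_occupancy(t, c(counts, arrest), total = params$N0,
                      model = "model1", params = params)
}

#' Expected state occupancy with symmetric self-renewal (model 2)
#'
#' With symmetric divisions at probability `p > 0` the pool grows linearly,
#' `N(t) = N0 * t*` with rescaled time `t* = (r p / N0) t + 1`, and the
#' expected occupancies are `N_i(t) = N0 * t* * dpois(i, lambda)` for
#' `i < c_states`, where `lambda = rho * ln(t*)` and `rho = (1 + p)/p`.
#' The arrest state is the remainder so the total is exactly `N0 * t*`.
#' As `p -> 0` this reduces continuously to [occupancy_model1()].
#'
#' @inheritParams occupancy_model1
#' @return A `state_occupancy` object (see [occupancy_model1()]).
#' @examples
#' pp <- stem_cell_params(N0 = 100, r = 100, p = 0.3, c_states = 7, delta_c = 0.05)
#' occupancy_model2(pp, t = 2)
#' @export
occupancy_model2 <- function(params, t) {
  stopifnot(inherits(params, "stem_cell_params"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop("t must be a single number >= 0")
  p <- params$p
  if (p < .P_EPS) return(occupancy_model1(params, t))
  cs <- params$c_states
  t_star <- params$r * p * t / params$N0 + 1
  lam <- (1 + p) / p * log1p(params$r * p * t / params$N0)
  total <- params$N0 * t_star
  counts <- total * stats::dpois(0:(cs - 1L), lam)
  arrest <- total * stats::ppois(cs - 1L, lam, lower.tail = FALSE)
  new_state_occupancy(t, c(counts, arrest), total = total,
                      model = "model2", params = params)
}

new_state_occupancy <- function(t, counts, total, model, params) {
  stopifnot(all(counts >= -1e-12))
  structure(list(t = t, counts = pmax(counts, 0), total = total,
                 model = model, params = params),
            class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat(sprintf("State occupancy (%s) at t = %g years: %d states, total = %g cells\n",
              x$model, x$t, length(x$counts), x$total))
  mode_i <- which.max(x$counts) - 1L
  cat(sprintf("  modal state %d (%g cells), arrest state holds %g cells\n",
              mode_i, max(x$counts), x$counts[length(x$counts)]))
  invisible(x)
}

#' @export
as.data.frame.state_occupancy <- function(x, ...) {
  data.frame(time = x$t, state = seq_along(x$counts) - 1L,
             length_kbp = state_length(x$params, seq_along(x$counts) - 1L),
             count = x$counts)
}

#' Rescaled time under a linearly growing stem-cell pool
#'
#' `t* = (r p / N0) t + 1`; equals 1 at `t = 0` and for `p = 0`.
#'
#' @inheritParams occupancy_model1
#' @return Dimensionless rescaled time (>= 1).
#' @export
t_star <- function(params, t) {
  stopifnot(inherits(params, "stem_cell_params"))
  params$r * params$p * t / params$N0 + 1
}
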