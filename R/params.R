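#' Mechanistic stem-cell parameter set
#'
#' Bundles the full parameter set of the division/arrest model: `N0` cells
#' start with telomeres of length `c0` kbp, the population performs `r` cell
#' divisions per year, each division is symmetric (two stem-cell daughters)
#' with probability `p` and shortens the daughters' telomeres by `delta_c`
#' kbp. After `c_states` divisions a cell reaches critically short telomeres
#' and enters permanent cell cycle arrest.
#'
#' The convention `c0 = c_states * delta_c` (the arrest state has zero
#' remaining length) is enforced on construction: give either `c_states` or
#' `c0` and the other is derived; if both are given they must agree.
#'
#' @param N0 initial stem-cell count (>= 1).
#' @param r total division rate of the population (divisions/year, > 0).
#' @param p probability that a division is symmetric, in `[0, 1]`.
#' @param c_states number of divisions until cycle arrest (integer >= 1).
#' @param delta_c telomere loss per division (kbp, > 0). Default 0.05 kbp,
#'   the commonly cited ~50 bp per division.
#' @param c0 initial mean telomere length (kbp, > 0).
#' @return An object of class `stem_cell_params`.
#' @examples
#' stem_cell_params(N0 = 100, r = 100, p = 0.3, c0 = 10.4)
#' @export
stem_cell_params <- function(N0, r, p, c_states = NULL, delta_c = 0.05,
                             c0 = NULL) {
  stopifnot(is.numeric(N0), length(N0) == 1L, N0 >= 1,
            is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(delta_c), length(delta_c) == 1L, delta_c > 0)
  if (is.null(c_states) && is.null(c0))
    stop("supply at least one of `c_states` or `c0`")
  if (is.null(c_states)) c_states <- as.integer(round(c0 / delta_c))
  c_states <- as.integer(c_states)
  if (c_states < 1) stop("`c_states` must be a positive integer")
  if (is.null(c0)) c0 <- c_states * delta_c
  if (abs(c0 - c_states * delta_c) > 1e-8 * max(1, c0))
    stop("inconsistent parameters: c0 must equal c_states * delta_c ",
         "(got c0 = ", c0, ", c_states * delta_c = ", c_states * delta_c, ")")
  structure(
    list(N0 = N0, r = r, p = p, c_states = c_states,
         delta_c = delta_c, c0 = c_states * delta_c),
    class = "stem_cell_params")
}

#' @export
print.stem_cell_params <- function(x, ...) {
  cat("Stem-cell model parameters\n")
  cat(sprintf("  N0 = %g cells, r = %g divisions/year, p(symmetric) = %g\n",
              x$N0, x$r, x$p))
  cat(sprintf("  c0 = %g kbp, delta_c = %g kbp/division, c_states = %d\n",
              x$c0, x$delta_c, x$c_states))
  invisible(x)
}

#' Population-scale (identifiable) parameter set
#'
#' Mean telomere length data on the cohort scale identifies only the
#' composite loss rate `kappa = delta_c * r / N0` (kbp/year), the initial
#' mean telomere length `c0` (kbp) and the symmetric-division probability
#' `p`; `N0`, `r` and `delta_c` are not separately identifiable from such
#' data. Cohort-level fitting functions therefore accept only this composite
#' set.
#'
#' @param kappa composite loss rate `delta_c * r / N0` (kbp/year, >= 0).
#' @param c0 initial mean telomere length (kbp, > 0).
#' @param p symmetric-division probability in `[0, 1]`.
#' @return An object of class `population_scale_params`.
#' @examples
#' population_scale_params(kappa = 0.075, c0 = 10.4, p = 0.35)
#' @export
population_scale_params <- function(kappa, c0, p) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
            is.numeric(c0), length(c0) == 1L, c0 > 0,
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(list(kappa = kappa, c0 = c0, p = p),
            class = "population_scale_params")
}

#' @export
print.population_scale_params <- function(x, ...) {
  cat(sprintf(
    "Population-scale parameters: kappa = %g kbp/year, c0 = %g kbp, p = %g\n",
    x$kappa, x$c0, x$p))
  invisible(x)
}

#' Reduce mechanistic parameters to the population-scale composites
#'
#' @param params a [stem_cell_params()] object.
#' @return A [population_scale_params()] object with
#'   `kappa = delta_c * r / N0`.
#' @export
as_population_scale <- function(params) {
  stopifnot(inherits(params, "stem_cell_params"))
  population_scale_params(kappa = params$delta_c * params$r / params$N0,
                          c0 = params$c0, p = params$p)
}

#' Telomere length of a division state
#'
#' State `i` holds cells that have divided `i` times, with remaining mean
#' telomere length `c0 - i * delta_c`; the arrest state `c_states` maps to
#' exactly zero.
#'
#' @param params a [stem_cell_params()] object.
#' @param i state index (vectorised), `0 <= i <= c_states`.
#' @return Telomere length(s) in kbp.
#' @examples
#' pp <- stem_cell_params(N0 = 100, r = 100, p = 0, c0 = 10, delta_c = 0.05)
#' state_length(pp, c(0, 40, 200))
#' @export
state_length <- function(params, i) {
  stopifnot(inherits(params, "stem_cell_params"))
  if (any(i < 0 | i > params$c_states) || any(i != round(i)))
    stop("state index out of range [0, ", params$c_states, "]")
  ifelse(i == params$c_states, 0, params$c0 - i * params$delta_c)
}

# threshold below which model-2 expressions switch to their p -> 0 limits
.P_EPS <- 1e-6
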