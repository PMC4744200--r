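#' Expected telomere length density of a single snapshot
#'
#' The normalised telomere length distribution observed in one individual at
#' rescaled time `t* = (r p / N0) t + 1`. Division counts are Poisson with
#' parameter `lambda = rho * ln(t*)`, `rho = (1 + p)/p`; a cell with `k`
#' divisions has length `x = c0 - k * delta_c`, so
#' `f(x) = lambda^k e^{-lambda} / Gamma(k + 1) / delta_c` with
#' `k = (c0 - x)/delta_c` generalised to continuous `x` through the gamma
#' function. Mass at `k > c_states = round(c0/delta_c)` (cells past arrest)
#' is truncated and the density renormalised over `[0, c0]`; the density is
#' zero for `x > c0`.
#'
#' Note the shape depends on `(t_star, p)` only through `lambda`; see
#' [fit_distribution()] for the inferential consequences.
#'
#' @param x telomere length(s) in kbp (vectorised).
#' @param t_star rescaled time, >= 1.
#' @param p symmetric-division probability in `(0, 1]`.
#' @param c0 initial telomere length (kbp).
#' @param delta_c telomere loss per division (kbp, default 0.05).
#' @return Probability density values (per kbp). At `t_star = 1` the
#'   distribution is degenerate at `c0`; numerically all mass is placed in
#'   the first division cell `[c0 - delta_c/2, c0]`.
#' @examples
#' xs <- seq(6, 10, by = 0.05)
#' fx <- telomere_density(xs, t_star = 2, p = 0.02, c0 = 10)
#' sum(fx) * 0.05  # ~ 1
#' @export
telomere_density <- function(x, t_star, p, c0, delta_c = 0.05) {
  stopifnot(length(t_star) == 1L, length(p) == 1L, length(c0) == 1L)
  if (!is.finite(t_star) || t_star < 1) stop("t_star must be >= 1")
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (c0 <= 0 || delta_c <= 0) stop("c0 and delta_c must be positive")
  lam <- (1 + p) / p * log(t_star)
  cs <- round(c0 / delta_c)
  if (lam == 0) {
    # degenerate wave at birth: all mass in the k = 0 cell
    return(ifelse(x <= c0 & x > c0 - delta_c / 2, 1 / (delta_c / 2), 0))
  }
  dens_raw <- function(xx) {
    k <- (c0 - xx) / delta_c
    out <- numeric(length(xx))
    ok <- xx <= c0 & xx >= 0 & k <= cs
    out[ok] <- exp(k[ok] * log(lam) - lam - lgamma(k[ok] + 1)) / delta_c
    out
  }
  # normalisation over the admissible support [0, c0] (truncation at arrest)
  grid <- seq(0, c0, length.out = 4096L)
  fg <- dens_raw(grid)
  z <- sum((fg[-1] + fg[-length(fg)]) / 2) * (grid[2] - grid[1])
  if (z <= 0) stop("degenerate density (no mass on support)")
  dens_raw(x) / z
}
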