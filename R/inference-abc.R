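# Approximate Bayesian computation by rejection sampling: draw composite
# parameters from uniform priors, realise the mean telomere length curve,
# score each realisation by R^2 against the cohort, and keep draws above a
# threshold (by default just below the best R^2 seen, emulating the use of
# a cutoff discovered from the observed maximum).

#' Uniform prior box for ABC
#'
#' Default ranges: `kappa` in `[0, 0.2]` kbp/year, `c0` in `[7, 15]` kbp,
#' `p` in `[0, 1]`, and (two-phase only) transition age `tT` in `[0, 80]`
#' years.
#'
#' @param kappa,c0,p,tT length-2 numeric ranges (lower, upper).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(kappa = c(0, 0.2), c0 = c(7, 15), p = c(0, 1),
                       tT = c(0, 80)) {
  rngs <- list(kappa = kappa, c0 = c0, p = p, tT = tT)
  for (nm in names(rngs)) {
    rg <- rngs[[nm]]
    if (length(rg) != 2 || !is.numeric(rg) || rg[1] >= rg[2])
      stop("prior range for ", nm, " must be (lower, upper) with lower < upper")
  }
  structure(rngs, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("ABC uniform priors:\n")
  cat(sprintf("  kappa in [%g, %g] kbp/year\n", x$kappa[1], x$kappa[2]))
  cat(sprintf("  c0    in [%g, %g] kbp\n", x$c0[1], x$c0[2]))
  cat(sprintf("  p     in [%g, %g]\n", x$p[1], x$p[2]))
  cat(sprintf("  tT    in [%g, %g] years (two-phase only)\n",
              x$tT[1], x$tT[2]))
  invisible(x)
}

runif_box <- function(n, rg) stats::runif(n, rg[1], rg[2])

# vectorised model-2 curve for a chunk of draws: returns n_obs x m matrix
m2_curve_chunk <- function(kappa, c0, p, t, delta_c) {
  # guard the p -> 0 limit columnwise
  m <- length(kappa)
  arg <- outer(t, kappa * p / delta_c)       # n x m
  lam <- log1p(arg) * rep((1 + p) / p, each = length(t))
  small <- p < .P_EPS
  if (any(small))
    lam[, small] <- outer(t, kappa[small] / delta_c)
  rep(c0, each = length(t)) - delta_c * lam
}

#' ABC rejection sampling on cohort mean telomere length
#'
#' Draws `n_draws` parameter sets i.i.d. from the uniform priors, realises
#' the mean telomere length curve of the chosen model at the cohort's ages,
#' scores each draw by [r_squared()] against the observed means, and
#' accepts draws according to `threshold_rule`. The default rule keeps
#' draws with `R^2 >= max(R^2) - 0.001`, reproducing the procedure of
#' fixing a cutoff just below the observed maximum; an absolute cutoff can
#' be supplied instead.
#'
#' @param sample a `population_sample` (columns `age_years`,
#'   `mean_tl_kbp`).
#' @param model 1, 2 or `"two_phase"`.
#' @param priors a [prior_spec()].
#' @param n_draws number of prior draws (>= 1000).
#' @param threshold_rule either `list(type = "relative", epsilon = 0.001)`
#'   (default) or `list(type = "absolute", cutoff = <R^2 value>)`.
#' @param seed integer RNG seed.
#' @param delta_c reference scale of the model-2 curve (kbp, default 1);
#'   see [mean_tl_approx()].
#' @param chunk_size draws evaluated per vectorised block (memory/speed
#'   trade-off).
#' @return An `abc_result`: accepted draw matrix with per-draw `r2`,
#'   `r2_max`, the threshold used, acceptance count and posterior
#'   summaries (mode, median, central 95% interval per parameter).
#' @examples
#' sc <- population_scale_params(kappa = 0.075, c0 = 10.4, p = 0.35)
#' pop <- generate_population(sc, n_subjects = 120, seed = 7)
#' abc_rejection(pop, model = 2, n_draws = 2e4, seed = 1)
#' @export
abc_rejection <- function(sample, model = 2, priors = prior_spec(),
                          n_draws = 1e5, threshold_rule = NULL, seed = 1,
                          delta_c = 1, chunk_size = 2e4) {
  check_population_sample(sample)
  stopifnot(inherits(priors, "prior_spec"), n_draws >= 1000)
  if (is.null(threshold_rule))
    threshold_rule <- list(type = "relative", epsilon = 0.001)
  two_phase <- identical(model, "two_phase") || identical(model, "two-phase")
  if (!two_phase) model <- match_model(model)

  t_obs <- sample$age_years
  y_obs <- sample$mean_tl_kbp
  sst <- sum((y_obs - mean(y_obs))^2)
  set.seed(as.integer(seed))

  par_names <- if (two_phase)
    c("kappa1", "c01", "p1", "kappa2", "c02", "p2", "tT")
  else if (model == 1L) c("kappa", "c0") else c("kappa", "c0", "p")

  r2_max <- -Inf
  kept <- list()
  n_done <- 0
  running_cut <- function() {
    if (threshold_rule$type == "absolute") threshold_rule$cutoff
    else r2_max - threshold_rule$epsilon
  }
  while (n_done < n_draws) {
    m <- min(chunk_size, n_draws - n_done)
    if (two_phase) {
      draws <- cbind(runif_box(m, priors$kappa), runif_box(m, priors$c0),
                     runif_box(m, priors$p), runif_box(m, priors$kappa),
                     runif_box(m, priors$c0), runif_box(m, priors$p),
                     runif_box(m, priors$tT))
      pred1 <- m2_curve_chunk(draws[, 1], draws[, 2], draws[, 3],
                              t_obs, delta_c)
      # phase 2 restarts its time origin at tT (column-specific shift)
      shift <- pmax(outer(t_obs, draws[, 7], "-"), 0)
      lam2 <- log1p(shift * rep(draws[, 4] * draws[, 6] / delta_c,
                                each = length(t_obs)))
      lam2 <- lam2 * rep((1 + draws[, 6]) / pmax(draws[, 6], .P_EPS),
                         each = length(t_obs))
      pred2 <- rep(draws[, 5], each = length(t_obs)) - delta_c * lam2
      in1 <- outer(t_obs, draws[, 7], "<=")
      pred <- ifelse(in1, pred1, pred2)
    } else if (model == 1L) {
      draws <- cbind(runif_box(m, priors$kappa), runif_box(m, priors$c0))
      pred <- rep(draws[, 2], each = length(t_obs)) -
        outer(t_obs, draws[, 1])
    } else {
      draws <- cbind(runif_box(m, priors$kappa), runif_box(m, priors$c0),
                     runif_box(m, priors$p))
      pred <- m2_curve_chunk(draws[, 1], draws[, 2], draws[, 3],
                             t_obs, delta_c)
    }
    r2 <- 1 - colSums((pred - y_obs)^2) / sst
    r2_max <- max(r2_max, max(r2))
    keep <- r2 >= running_cut()
    if (any(keep))
      kept[[length(kept) + 1L]] <- cbind(draws[keep, , drop = FALSE],
                                         r2 = r2[keep])
    n_done <- n_done + m
  }
  acc <- do.call(rbind, kept)
  threshold <- running_cut()
  acc <- acc[acc[, "r2"] >= threshold, , drop = FALSE]
  if (is.null(acc) || nrow(acc) == 0)
    stop("zero acceptances; loosen the threshold rule ",
         "(larger epsilon or lower absolute cutoff)")
  colnames(acc) <- c(par_names, "r2")

  marg <- function(v) {
    md <- if (length(unique(v)) > 5) {
      d <- stats::density(v)
      d$x[which.max(d$y)]
    } else stats::median(v)
    c(mode = md, median = stats::median(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))
  }
  summaries <- t(vapply(par_names, function(nm) marg(acc[, nm]),
                        numeric(4)))

  structure(list(model = if (two_phase) "two_phase" else
                   paste0("model", model),
                 accepted = acc[, par_names, drop = FALSE],
                 r2 = acc[, "r2"], r2_max = r2_max,
                 threshold = threshold, threshold_rule = threshold_rule,
                 n_draws = n_draws, n_accepted = nrow(acc),
                 posterior = summaries, priors = priors,
                 seed = as.integer(seed), delta_c = delta_c),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf(
    "ABC rejection (%s): %d / %g draws accepted (R^2 max %.4f, cutoff %.4f)\n",
    x$model, x$n_accepted, x$n_draws, x$r2_max, x$threshold))
  print(round(x$posterior, 4))
  invisible(x)
}

#' Export accepted ABC draws as CSV
#'
#' @param result an [abc_rejection()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abc_csv <- function(result, path) {
  stopifnot(inherits(result, "abc_result"))
  utils::write.csv(cbind(as.data.frame(result$accepted), r2 = result$r2),
                   path, row.names = FALSE)
  invisible(path)
}
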