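# File formats and pipeline orchestration. Canonical tabular format is CSV
# with a one-line header; nested results are JSON; run configuration is a
# YAML file mirroring the function arguments.

#' Read / write cohort mean telomere length tables
#'
#' Column schema: `subject_id`, `age_years`, `cell_type` (one of
#' `lymphocyte`, `granulocyte`, `bone_marrow`), `mean_tl_kbp`. Reading
#' validates the schema and the record invariants (ages in `[0, 120]`,
#' positive telomere lengths, subject unique per cell type) and reports
#' offending row numbers. Writing round-trips losslessly; if the sample
#' carries generating truth it is stored in a sidecar JSON
#' (`<path>.truth.json`).
#'
#' @param path CSV file path.
#' @return `read_population_csv()`: a `population_sample` data.frame.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "cell_type", "mean_tl_kbp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$cell_type %in% CELL_TYPES)
  if (length(bad))
    stop("unknown cell_type ", sQuote(df$cell_type[bad[1]]),
         " at row ", bad[1], "; expected one of ",
         paste(CELL_TYPES, collapse = ", "))
  bad <- which(!is.finite(df$age_years) | df$age_years < 0 |
                 df$age_years > 120)
  if (length(bad)) stop("invalid age_years at row ", bad[1])
  bad <- which(!is.finite(df$mean_tl_kbp) | df$mean_tl_kbp <= 0)
  if (length(bad)) stop("invalid mean_tl_kbp at row ", bad[1])
  if (anyDuplicated(df[c("subject_id", "cell_type")]))
    stop("duplicate subject_id within a cell type")
  truth_path <- paste0(path, ".truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(df, truth = truth,
            class = c("population_sample", "data.frame"))
}

#' @rdname read_population_csv
#' @param sample the `population_sample` to write.
#' @export
write_population_csv <- function(sample, path) {
  stopifnot(is.data.frame(sample))
  utils::write.csv(as.data.frame(sample)[, c("subject_id", "age_years",
                                             "cell_type", "mean_tl_kbp")],
                   path, row.names = FALSE)
  truth <- attr(sample, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write per-cell telomere length tables
#'
#' Column schema: `subject_id`, `age_years`, `cell_type`, `cell_tl_kbp`
#' (one row per measured cell). A file may contain several subjects;
#' reading returns a list of `individual_sample` objects (a single object
#' if only one subject is present).
#'
#' @param path CSV file path.
#' @return `read_individual_csv()`: an `individual_sample` or list thereof.
#' @export
read_individual_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "cell_type", "cell_tl_kbp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$cell_type %in% CELL_TYPES)
  if (length(bad))
    stop("unknown cell_type ", sQuote(df$cell_type[bad[1]]),
         " at row ", bad[1])
  bad <- which(!is.finite(df$age_years) | df$age_years < 0 |
                 df$age_years > 120)
  if (length(bad)) stop("invalid age_years at row ", bad[1])
  bad <- which(!is.finite(df$cell_tl_kbp) | df$cell_tl_kbp < 0)
  if (length(bad)) stop("invalid cell_tl_kbp at row ", bad[1])
  out <- lapply(split(df, df$subject_id), function(g) {
    structure(list(subject_id = g$subject_id[1], age = g$age_years[1],
                   cell_type = g$cell_type[1], cell_tl = g$cell_tl_kbp,
                   truth = NULL),
              class = "individual_sample")
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_individual_csv
#' @param sample an `individual_sample` (or list of them) to write.
#' @export
write_individual_csv <- function(sample, path) {
  if (inherits(sample, "individual_sample")) sample <- list(sample)
  df <- do.call(rbind, lapply(sample, function(s)
    data.frame(subject_id = s$subject_id, age_years = s$age,
               cell_type = s$cell_type, cell_tl_kbp = s$cell_tl,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# tiny polynomial rolling hash of the serialised configuration, for
# artifact provenance (exact arithmetic in doubles below 2^53)
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline run configuration
#'
#' A YAML file mirroring [run_pipeline()]'s `config` list; every stochastic
#' step must carry an explicit or defaulted `seed`.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run a generation / fitting / selection pipeline
#'
#' Chains the package's steps according to a configuration list. Supported
#' step commands: `synth-pop`, `synth-ind`, `simulate`, `fit-mean`,
#' `fit-dist`, `abc`, `select`. Each step writes a versioned JSON result
#' (and CSV where tabular) into `config$out_dir`, stamped with the seed,
#' the configuration hash and the runtime; `select` consumes the fits of
#' previous `fit-mean` steps. Re-running the same configuration and seed
#' reproduces identical artifacts (timestamps aside).
#'
#' @param config a list (e.g. from [read_run_config()]) with fields
#'   `out_dir`, `seed`, and `steps`: a list of step lists, each with `cmd`
#'   plus command-specific arguments (`n_subjects`, `model`, `n_draws`,
#'   `truth = list(kappa, c0, p)`, ...).
#' @return Named list of result objects per step, invisibly; artifacts on
#'   disk.
#' @examples
#' cfg <- list(out_dir = tempfile("run"), seed = 11, steps = list(
#'   list(cmd = "synth-pop", n_subjects = 80,
#'        truth = list(kappa = 0.075, c0 = 10.4, p = 0.35)),
#'   list(cmd = "fit-mean", model = 2, n_boot = 20),
#'   list(cmd = "fit-mean", model = 1, n_boot = 20),
#'   list(cmd = "select")))
#' res <- run_pipeline(cfg)
#' res$`step3_fit-mean`$estimates
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$steps))
  if (is.null(config$seed)) config$seed <- 1L
  out_dir <- config$out_dir %||% "telodyn-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  seed <- as.integer(config$seed)

  results <- list()
  pop <- NULL
  ind <- NULL
  fits <- list()

  stamp_write <- function(obj, name, payload) {
    path <- file.path(out_dir, paste0(name, ".json"))
    payload$meta <- list(step = name, seed = seed, config_hash = hash,
                         runtime_s = payload$meta_runtime,
                         package_version =
                           as.character(utils::packageVersion("telodyn")))
    payload$meta_runtime <- NULL
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    path
  }

  for (k in seq_along(config$steps)) {
    step <- config$steps[[k]]
    name <- paste0("step", k, "_", step$cmd)
    t0 <- proc.time()[["elapsed"]]
    res <- switch(
      step$cmd,
      "synth-pop" = {
        tr <- step$truth %||% list(kappa = 0.075, c0 = 10.4, p = 0.35)
        sc <- population_scale_params(tr$kappa, tr$c0, tr$p)
        pop <- generate_population(
          sc, n_subjects = step$n_subjects %||% 356,
          baseline_sd = step$baseline_sd %||% 0.5,
          noise_sd = step$noise_sd %||% 0.3,
          cell_type = step$cell_type %||% "lymphocyte",
          seed = step$seed %||% seed)
        write_population_csv(pop, file.path(out_dir, paste0(name, ".csv")))
        pop
      },
      "synth-ind" = {
        tr <- step$truth %||% list(N0 = 100, r = 125, p = 0.02, c0 = 10)
        pp <- stem_cell_params(tr$N0, tr$r, tr$p, c0 = tr$c0,
                               delta_c = step$delta_c %||% 0.05)
        ind <- generate_individual(
          pp, age = step$age %||% 40, n_cells = step$n_cells %||% 1000,
          cell_noise_sd = step$cell_noise_sd %||% 1.0,
          seed = step$seed %||% seed)
        write_individual_csv(ind, file.path(out_dir, paste0(name, ".csv")))
        ind
      },
      "simulate" = {
        tr <- step$truth %||% list(N0 = 100, r = 100, p = 0, c_states = 7)
        pp <- stem_cell_params(tr$N0, tr$r, tr$p,
                               c_states = tr$c_states,
                               delta_c = step$delta_c %||% 0.05)
        traj <- simulate_population(pp, t_end = step$t_end %||% 5,
                                    checkpoints = step$checkpoints %||%
                                      seq(1, step$t_end %||% 5),
                                    seed = step$seed %||% seed)
        write_trajectory_csv(traj, file.path(out_dir, paste0(name, ".csv")))
        traj
      },
      "fit-mean" = {
        if (is.null(pop)) {
          if (is.null(step$input)) stop("fit-mean: no upstream cohort; ",
                                        "run synth-pop first or give `input`")
          pop <- read_population_csv(step$input)
        }
        f <- if (identical(step$model, "two_phase"))
          fit_two_phase(pop, n_boot = step$n_boot %||% 200,
                        seed = step$seed %||% seed)
        else fit_mean_model(pop, model = step$model %||% 2,
                            n_boot = step$n_boot %||% 1000,
                            seed = step$seed %||% seed)
        fits[[length(fits) + 1L]] <- f
        f
      },
      "fit-dist" = {
        if (is.null(ind)) {
          if (is.null(step$input)) stop("fit-dist: no upstream individual ",
                                        "sample; run synth-ind first or give `input`")
          ind <- read_individual_csv(step$input)
        }
        fit_distribution(ind, n_boot = step$n_boot %||% 200,
                         seed = step$seed %||% seed)
      },
      "abc" = {
        if (is.null(pop)) {
          if (is.null(step$input)) stop("abc: no upstream cohort; ",
                                        "run synth-pop first or give `input`")
          pop <- read_population_csv(step$input)
        }
        ab <- abc_rejection(pop, model = step$model %||% 2,
                            n_draws = step$n_draws %||% 1e5,
                            seed = step$seed %||% seed)
        write_abc_csv(ab, file.path(out_dir, paste0(name, ".csv")))
        ab
      },
      "select" = {
        if (length(fits) < 2)
          stop("select: needs at least two upstream fit-mean steps")
        model_select(fits)
      },
      stop("unknown pipeline command: ", step$cmd))
    dt <- proc.time()[["elapsed"]] - t0
    payload <- serialise_result(res)
    payload$meta_runtime <- round(dt, 3)
    stamp_write(res, name, payload)
    results[[name]] <- res
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-friendly view of the package's result objects
serialise_result <- function(x) {
  if (inherits(x, "mean_fit"))
    return(list(kind = "mean_fit", model = x$model,
                estimates = as.list(x$estimates),
                ci = if (!is.null(x$ci)) as.data.frame(x$ci),
                rss = x$rss, r2 = x$r2, n = x$n, k = x$k,
                logL = x$logL, aic = x$aic, bic = x$bic,
                seed = x$seed))
  if (inherits(x, "dist_fit"))
    return(list(kind = "dist_fit", subject_id = x$subject_id,
                age = x$age, cell_type = x$cell_type,
                estimates = as.list(x$estimates),
                ci = if (!is.null(x$ci)) as.data.frame(x$ci),
                r_over_N0 = x$r_over_N0,
                loss_rate_bp_per_year = x$loss_rate_bp_per_year,
                r2 = x$r2, degenerate = x$degenerate,
                boundary = x$boundary, seed = x$seed))
  if (inherits(x, "abc_result"))
    return(list(kind = "abc_result", model = x$model,
                n_draws = x$n_draws, n_accepted = x$n_accepted,
                r2_max = x$r2_max, threshold = x$threshold,
                posterior = as.data.frame(x$posterior),
                seed = x$seed))
  if (inherits(x, "model_selection"))
    return(list(kind = "model_selection", table = as.data.frame(x)))
  if (inherits(x, "trajectory"))
    return(list(kind = "trajectory", seed = x$seed,
                checkpoints = x$checkpoints,
                population_sizes = x$population_sizes))
  if (inherits(x, "population_sample"))
    return(list(kind = "population_sample", n = nrow(x),
                age_range = range(x$age_years),
                per_type = as.list(table(x$cell_type)),
                truth = attr(x, "truth")))
  if (inherits(x, "individual_sample"))
    return(list(kind = "individual_sample", subject_id = x$subject_id,
                age = x$age, n_cells = length(x$cell_tl),
                truth = x$truth))
  list(kind = class(x)[1])
}
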