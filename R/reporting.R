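#' Derive mixture weights, compartment volumes and C1(0) from a config
#'
#' Runs the deterministic part of the pipeline — histomorphometry to
#' area ratios to mixture weights, physiology to compartment volumes —
#' and reports each quantity at full precision alongside the rounded
#' presentation value (weights to 3 decimals, volumes to whole mL,
#' concentrations to 2 decimals).
#'
#' @param config A `run_config`, YAML path, or list
#'   (see [read_run_config()]).
#' @param out Optional path; when given, the report is written there as
#'   JSON (including the config hash).
#' @return List of class `derive_report`: `ratios`, `volumes`, `C1_0`,
#'   `areas`, and a `table` data frame with `quantity`, `value`,
#'   `printed` columns.
#' @examples
#' run_derive(system.file("extdata", "canine.yaml", package = "myopk"))
#' @export
run_derive <- function(config, out = NULL) {
  config <- as_run_config(config)
  areas <- area_ratios(config$histology)
  ratios <- volume_ratios(areas)
  dv <- derive_volumes(config$subject, areas)
  v <- unclass(dv$volumes)
  r <- unclass(ratios)
  tab <- data.frame(
    quantity = c("plasma_area_pct", "interstitial_area_pct",
                 "cell_area_pct", "R1", "R2", "R3",
                 "V1_ml", "V2_ml", "V3_ml", "C1_0_ug_ml"),
    value = c(unclass(areas)[c("plasma_pct", "interstitial_pct",
                               "cell_pct")],
              r, v, dv$C1_0),
    printed = c(round(unclass(areas)[c("plasma_pct", "interstitial_pct",
                                       "cell_pct")], 2),
                round(r, 3), round(v), round(dv$C1_0, 2)))
  rep <- structure(list(ratios = ratios, volumes = dv$volumes,
                        C1_0 = dv$C1_0, areas = areas, table = tab,
                        config_hash = config$hash),
                   class = "derive_report")
  if (!is.null(out)) {
    jsonlite::write_json(
      list(config_hash = config$hash,
           areas = as.list(unclass(areas)),
           ratios = as.list(r), volumes = as.list(v),
           C1_0 = dv$C1_0, table = tab),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

#' @export
print.derive_report <- function(x, ...) {
  cat("Derived mixture weights and compartment volumes\n")
  tab <- x$table
  tab$value <- signif(tab$value, 6)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Simulate a trajectory from a config and write it as CSV
#'
#' Thin orchestration over [pk_simulate()]: volumes, C1(0) and mixture
#' weights come from the config, rate constants from `k` (default: the
#' design's ground truth).  Output columns are `time_min, C1, C2, C3,
#' Cmyo`.
#'
#' @param config A `run_config`, YAML path, or list.
#' @param k Named rate constants, 1/min.
#' @param times Simulation times, minutes (default 0.5-min grid to the
#'   last plasma sample).
#' @param out Optional CSV path.
#' @return The trajectory data frame (invisibly if `out` given), with
#'   a `Cmyo` column appended.
#' @export
run_simulate <- function(config, k = NULL, times = NULL, out = NULL) {
  config <- as_run_config(config)
  der <- run_derive(config)
  if (is.null(k)) k <- config$design$true_k
  if (is.null(times))
    times <- seq(0, max(config$design$plasma_times_min), by = 0.5)
  params <- compartment_params(der$volumes, k[["k10"]], k[["k12"]],
                               k[["k21"]], k[["k23"]], k[["k32"]])
  traj <- pk_simulate(params, der$C1_0, times)
  traj$Cmyo <- myocardial_concentration(traj, der$ratios)
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(traj), out, row.names = FALSE)
    return(invisible(traj))
  }
  traj
}

#' Generate a synthetic observation set and write the study artifacts
#'
#' Writes `plasma.csv` and `fluor.csv` (columns `time_min,value`) and
#' `truth.json` (ground-truth parameters, volumes, weights, config
#' hash) under `out_dir`.
#'
#' @param config A `run_config`, YAML path, or list.
#' @param out_dir Output directory, created if missing.
#' @return The `pk_sim` object, invisibly.
#' @export
run_generate <- function(config, out_dir) {
  config <- as_run_config(config)
  sim <- generate_observations(config$design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$observations$plasma,
                   file.path(out_dir, "plasma.csv"), row.names = FALSE)
  utils::write.csv(sim$observations$fluorescence,
                   file.path(out_dir, "fluor.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config$hash,
         k = as.list(sim$truth$k), Rmyo = sim$truth$Rmyo,
         volumes = as.list(unclass(sim$truth$volumes)),
         ratios = as.list(unclass(sim$truth$ratios)),
         C1_0 = sim$truth$C1_0, n_truncated = sim$truth$n_truncated,
         seed = config$design$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(sim)
}

#' Fit the model from a config, optionally reading observation CSVs
#'
#' When `plasma_csv`/`fluor_csv` are given they are read as
#' `time_min,value` tables; otherwise a synthetic observation set is
#' generated from the config's design.  The fit result is serialized
#' to JSON (estimates, Rmyo, fval, R-squared, convergence and
#' identifiability diagnostics, per-start log, config hash) when `out`
#' is supplied.
#'
#' @param config A `run_config`, YAML path, or list.
#' @param plasma_csv,fluor_csv Optional CSV paths.
#' @param out Optional JSON output path.
#' @return The `pk3_fit` object.
#' @export
run_fit <- function(config, plasma_csv = NULL, fluor_csv = NULL,
                    out = NULL) {
  config <- as_run_config(config)
  der <- run_derive(config)
  if (is.null(plasma_csv) != is.null(fluor_csv))
    stop("supply both `plasma_csv` and `fluor_csv`, or neither",
         call. = FALSE)
  if (!is.null(plasma_csv)) {
    for (f in c(plasma_csv, fluor_csv))
      if (!file.exists(f))
        stop("observation file not found: ", f, call. = FALSE)
    obs <- observation_set(utils::read.csv(plasma_csv),
                           utils::read.csv(fluor_csv),
                           C1_0 = der$C1_0)
  } else {
    obs <- generate_observations(config$design)$observations
  }
  fit <- do.call(fit_rate_constants,
                 c(list(observations = obs, volumes = der$volumes,
                        ratios = der$ratios), config$fit))
  if (!is.null(out)) {
    jsonlite::write_json(
      list(config_hash = config$hash,
           k = as.list(fit$k), Rmyo = fit$Rmyo, fval = fit$fval,
           r_squared = fit$r_squared, converged = fit$converged,
           n_iterations = fit$n_iterations, n_starts = fit$n_starts,
           best_start = fit$best_start, seed = fit$seed,
           identifiability = as.list(fit$identifiability),
           starts = fit$starts),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fit
}

#' Run a parameter-recovery experiment from a config
#'
#' @param config A `run_config`, YAML path, or list.
#' @param n_replicates Number of simulated-and-refitted replicates.
#' @param out Optional JSON output path.
#' @return The `recovery_report`.
#' @export
run_recover <- function(config, n_replicates = 20, out = NULL) {
  config <- as_run_config(config)
  opts <- config$fit
  rep <- recovery_experiment(config$design, n_replicates = n_replicates,
                             n_starts = opts$n_starts %||% 20,
                             k_max = opts$k_max %||% 10,
                             maxit = opts$maxit %||% 500)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(config_hash = config$hash,
           true_k = as.list(rep$true_k),
           bias = as.list(rep$bias),
           relative_rmse = as.list(rep$relative_rmse),
           r_squared = rep$r_squared,
           failure_rate = rep$failure_rate,
           n_replicates = rep$n_replicates),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else read_run_config(config)
}
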