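#' Read and validate a run configuration
#'
#' A single YAML (or already-parsed list) configuration drives every
#' pipeline entry point.  Recognised blocks:
#'
#' * `histology`: fields of [histology_measurements()].
#' * `subject`: fields of [subject_profile()].
#' * `design`: sampling schedules, noise model and ground truth for
#'   [study_design()] (optional; defaults to the canine design).
#' * `fit`: options for [fit_rate_constants()] (optional).
#' * `seed`: integer, funnels all randomness (optional, default 1;
#'   a `seed` inside `design`/`fit` overrides it per stage).
#'
#' Validation failures report the offending field path
#' (e.g. `histology$hematocrit`).
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list of class `run_config` with constructed
#'   `histology`, `subject` and `design` objects and a `hash` field
#'   (md5 of the canonical JSON rendering, for provenance).
#' @examples
#' cfg <- read_run_config(system.file("extdata", "canine.yaml",
#'                                    package = "myopk"))
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("`config` must be a YAML path or a named list", call. = FALSE)

  hash <- config_hash(config)
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("invalid config field `seed`: must be a single integer",
         call. = FALSE)

  hist <- with_field_context("histology", {
    h <- config$histology %||% list()
    do.call(histology_measurements, modifyList(list(
      vessel_area_ratio_pct = 12.3, hematocrit = 0.45,
      cell_area_ratio_pct = 61.7), h))
  })
  subj <- with_field_context("subject", {
    s <- config$subject %||% list()
    do.call(subject_profile, modifyList(list(
      body_weight_kg = 9.3, dose_mg_per_kg = 2.5), s))
  })
  des <- with_field_context("design", {
    d <- config$design %||% list()
    if (!is.null(d$true_k)) d$true_k <- unlist(d$true_k)
    if (!is.null(d$plasma_times_min))
      d$plasma_times_min <- as.numeric(unlist(d$plasma_times_min))
    if (!is.null(d$fluorescence_times_min))
      d$fluorescence_times_min <- as.numeric(unlist(d$fluorescence_times_min))
    if (is.null(d$seed)) d$seed <- seed
    do.call(study_design, c(d, list(subject = subj, histology = hist)))
  })
  fit_opts <- config$fit %||% list()
  allowed <- c("n_starts", "seed", "k_max", "rmyo_ref_time", "maxit")
  bad <- setdiff(names(fit_opts), allowed)
  if (length(bad))
    stop("unknown config field(s): ",
         paste0("fit$", bad, collapse = ", "), call. = FALSE)
  if (is.null(fit_opts$seed)) fit_opts$seed <- seed

  structure(list(histology = hist, subject = subj, design = des,
                 fit = fit_opts, seed = as.integer(seed), hash = hash),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# prefix validation errors with the config block path
with_field_context <- function(block, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("invalid config block `%s`: %s", block,
                 conditionMessage(e)), call. = FALSE))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (hash ", substr(x$hash, 1, 8), ")\n", sep = "")
  print(x$subject)
  print(x$histology)
  print(x$design)
  invisible(x)
}
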