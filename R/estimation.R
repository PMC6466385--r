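#' Observation set: plasma concentrations and myocardial fluorescence
#'
#' Couples the two measured streams the model is fitted to: plasma
#' concentration (ug/mL) at the blood-sampling times and relative
#' myocardial fluorescence (counts) at the probe-reading times, plus
#' the subject linkage that fixes the initial plasma concentration
#' C1(0) = dose / V1.
#'
#' Rows are sorted by time on construction (duplicate times are
#' rejected), so downstream results do not depend on row order.
#'
#' @param plasma Data frame with columns `time_min`, `value` (ug/mL).
#'   At least two points beyond t = 0.
#' @param fluorescence Data frame with columns `time_min`, `value`
#'   (relative counts).  At least one point beyond t = 0.
#' @param C1_0 Initial plasma concentration, ug/mL (from
#'   [derive_volumes()] or [initial_plasma_concentration()]).
#' @return Object of class `observation_set`.
#' @export
observation_set <- function(plasma, fluorescence, C1_0) {
  chk <- function(d, name, min_after0) {
    if (!is.data.frame(d) || !all(c("time_min", "value") %in% names(d)))
      stop_bad_arg(name, "must be a data frame with columns time_min, value")
    d <- d[order(d$time_min), , drop = FALSE]
    row.names(d) <- NULL
    check_times(d$time_min, paste0(name, "$time_min"))
    if (anyNA(d$value)) stop_bad_arg(name, "contains NA values")
    if (sum(d$time_min > 0) < min_after0)
      stop_bad_arg(name, sprintf(
        "needs at least %d point(s) after t = 0", min_after0))
    d[c("time_min", "value")]
  }
  plasma <- chk(plasma, "plasma", 2L)
  fluorescence <- chk(fluorescence, "fluorescence", 1L)
  check_number(C1_0, "C1_0", 0)
  structure(list(plasma = plasma, fluorescence = fluorescence, C1_0 = C1_0),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf(
    "Observation set: %d plasma points (%g-%g min), %d fluorescence points, C1(0) = %.4g ug/mL\n",
    nrow(x$plasma), min(x$plasma$time_min), max(x$plasma$time_min),
    nrow(x$fluorescence), x$C1_0))
  invisible(x)
}

#' Fluorescence conversion constant from the t = 0 match
#'
#' At the bolus instant the peripheral compartments are empty, so the
#' model's myocardial concentration is `Cmyo(0) = R1 * C1(0)`.  The
#' conversion constant is chosen to make the converted fluorescence
#' reading at the reference time equal that value:
#' `Rmyo = R1 * C1(0) / Mmyo(0)`.
#'
#' @param C1_0 Initial plasma concentration, ug/mL.
#' @param R1 Plasma volume ratio (first element of [volume_ratios()]).
#' @param Mmyo_at_t0 Fluorescence reading at the reference time,
#'   counts, > 0.
#' @return Rmyo, ug/(mL * counts).
#' @examples
#' compute_rmyo(59.01, 0.08, 0.024979) # about 189
#' @export
compute_rmyo <- function(C1_0, R1, Mmyo_at_t0) {
  check_number(C1_0, "C1_0", 0)
  check_number(R1, "R1", 0, 1)
  if (!is.numeric(Mmyo_at_t0) || length(Mmyo_at_t0) != 1L ||
      !is.finite(Mmyo_at_t0) || Mmyo_at_t0 <= 0)
    stop("fluorescence at the reference time must be > 0; ",
         "choose an alternate reference time (`rmyo_ref_time`) with a ",
         "positive reading", call. = FALSE)
  (R1 * C1_0) / Mmyo_at_t0
}

#' Least-squares objective (fval)
#'
#' Sum of the per-stream mean squared errors between observations and
#' model predictions: plasma against C1 and converted fluorescence
#' (`Rmyo * Mmyo`) against the mixture Cmyo, each divided by its own
#' number of points.  Units: (ug/mL)^2.
#'
#' @param k Named numeric of the five rate constants (`k10`, `k12`,
#'   `k21`, `k23`, `k32`), all >= 0.
#' @param observations An [observation_set()].
#' @param volumes A [compartment_volumes()].
#' @param ratios A [volume_ratios()].
#' @param Rmyo Conversion constant, fixed before evaluation.
#' @return fval, a nonnegative scalar.
#' @export
pk_objective <- function(k, observations, volumes, ratios, Rmyo) {
  stopifnot(inherits(observations, "observation_set"))
  if (any(k < 0)) stop("rate constants must be nonnegative", call. = FALSE)
  check_number(Rmyo, "Rmyo", 0, strict_lower = TRUE)
  fn <- make_objective(observations, volumes, ratios, Rmyo)
  fn(k[c("k10", "k12", "k21", "k23", "k32")])
}

# fast closure used inside the optimizer: same fval as pk_objective but
# without per-evaluation container construction
make_objective <- function(observations, volumes, ratios, Rmyo) {
  V <- as.numeric(unclass(volumes))
  r <- as.numeric(unclass(ratios))
  tp <- observations$plasma$time_min
  tf <- observations$fluorescence$time_min
  tt <- sort(unique(c(0, tp, tf)))
  ip <- match(tp, tt)
  im <- match(tf, tt)
  y_pla <- observations$plasma$value
  y_myo <- Rmyo * observations$fluorescence$value
  a0 <- c(V[1] * observations$C1_0, 0, 0)
  function(k) {
    M <- matrix(c(-(k[1] + k[2]), k[2], 0,
                  k[3], -(k[3] + k[4]), k[4],
                  0, k[5], -k[5]), 3, 3)
    A <- expm_apply(M, a0, tt)
    C <- A / V
    c1 <- C[1, ip]
    cmyo <- r[1] * C[1, im] + r[2] * C[2, im] + r[3] * C[3, im]
    mean((y_pla - c1)^2) + mean((y_myo - cmyo)^2)
  }
}

# one L-BFGS-B start; returns par, value, convergence info
run_one_start <- function(par0, fn, k_max, maxit) {
  o <- stats::optim(par0, fn, method = "L-BFGS-B",
                    lower = rep(0, 5), upper = rep(k_max, 5),
                    control = list(factr = 1e3, pgtol = 1e-12,
                                   maxit = maxit,
                                   ndeps = rep(1e-7, 5)))
  # polish: a short Nelder-Mead pass escapes finite-difference plateaus,
  # then a final bounded pass re-imposes the constraints
  nm <- stats::optim(o$par, function(p) {
    if (any(p < 0) || any(p > k_max)) return(Inf)
    fn(p)
  }, method = "Nelder-Mead",
    control = list(maxit = 500, reltol = 1e-14))
  if (nm$value < o$value) {
    o2 <- stats::optim(pmin(pmax(nm$par, 0), k_max), fn,
                       method = "L-BFGS-B",
                       lower = rep(0, 5), upper = rep(k_max, 5),
                       control = list(factr = 1e3, pgtol = 1e-12,
                                      maxit = maxit,
                                      ndeps = rep(1e-7, 5)))
    if (o2$value < nm$value) o <- o2
    else o <- list(par = pmin(pmax(nm$par, 0), k_max), value = nm$value,
                   convergence = o$convergence, counts = o$counts)
  }
  o
}

#' Fit the five rate constants to an observation set
#'
#' Multi-start bound-constrained least squares: the conversion constant
#' Rmyo is first fixed from the reference-time fluorescence match
#' ([compute_rmyo()]), then the five rate constants are estimated by
#' minimizing [pk_objective()] with L-BFGS-B under bounds
#' `[0, k_max]`, from `n_starts` log-uniform random initial points (a
#' short derivative-free polish guards against finite-difference
#' stalls).  The best start wins; the whole procedure is deterministic
#' given `seed`.
#'
#' @param observations An [observation_set()].
#' @param volumes A [compartment_volumes()].
#' @param ratios A [volume_ratios()].
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed for the start draws.
#' @param k_max Upper bound on every rate constant, 1/min.
#' @param start_range Range of the log-uniform start distribution,
#'   1/min.
#' @param rmyo_ref_time Time (min) of the fluorescence reading used to
#'   fix Rmyo; default 0 (the post-bolus reading).
#' @param maxit Iteration cap per start.
#' @return Object of class `pk3_fit` with components `k` (named
#'   estimates), `Rmyo`, `fval`, `r_squared`, `converged`,
#'   `n_iterations`, `n_starts`, `best_start`, `seed`, `starts`
#'   (per-start log), `identifiability` (curvature-based flags),
#'   and the inputs needed by the methods.
#' @seealso [predict.pk3_fit()], [summary.pk3_fit()],
#'   [summarize_interstitial()]
#' @export
fit_rate_constants <- function(observations, volumes, ratios,
                               n_starts = 20, seed = 1, k_max = 10,
                               start_range = c(1e-4, 1),
                               rmyo_ref_time = 0, maxit = 500) {
  stopifnot(inherits(observations, "observation_set"))
  check_number(n_starts, "n_starts", 1)
  check_number(k_max, "k_max", 0, strict_lower = TRUE)

  iref <- match(rmyo_ref_time, observations$fluorescence$time_min)
  if (is.na(iref))
    stop("no fluorescence reading at `rmyo_ref_time` = ", rmyo_ref_time,
         call. = FALSE)
  Rmyo <- compute_rmyo(observations$C1_0, unclass(ratios)[[1]],
                       observations$fluorescence$value[iref])

  knames <- c("k10", "k12", "k21", "k23", "k32")
  fn <- make_objective(observations, volumes, ratios, Rmyo)

  set.seed(seed)
  starts <- matrix(10^stats::runif(5L * n_starts,
                                   log10(start_range[1]),
                                   log10(start_range[2])),
                   nrow = n_starts, dimnames = list(NULL, knames))

  log_rows <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fval0 <- fn(starts[i, ])
    o <- tryCatch(run_one_start(starts[i, ], fn, k_max, maxit),
                  error = function(e) e)
    if (inherits(o, "error")) {
      log_rows[[i]] <- data.frame(start = i, fval_init = fval0,
                                  fval = NA_real_, convergence = NA_integer_,
                                  error = conditionMessage(o))
      next
    }
    log_rows[[i]] <- data.frame(start = i, fval_init = fval0,
                                fval = o$value,
                                convergence = o$convergence,
                                error = NA_character_)
    if (is.null(best) || o$value < best$value) {
      best <- o
      best$start <- i
    }
  }
  starts_log <- do.call(rbind, log_rows)
  if (is.null(best)) {
    stop("all optimizer starts failed:\n",
         paste(utils::capture.output(print(starts_log)), collapse = "\n"),
         call. = FALSE)
  }

  k_hat <- structure(as.numeric(best$par), names = knames)

  # curvature-based identifiability flags: a parameter whose diagonal
  # curvature is tiny relative to the largest (or which sits on a bound)
  # is effectively unconstrained by the data
  H <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
  ident <- rep(TRUE, 5L)
  names(ident) <- knames
  if (!is.null(H)) {
    d <- abs(diag(H))
    ident <- d > 1e-8 * max(d, .Machine$double.eps)
  }
  ident <- ident & (k_hat > 0) & (k_hat < k_max)

  # goodness of fit on pooled streams
  p_hat <- compartment_params(volumes, k_hat[["k10"]], k_hat[["k12"]],
                              k_hat[["k21"]], k_hat[["k23"]],
                              k_hat[["k32"]])
  tp <- observations$plasma$time_min
  tf <- observations$fluorescence$time_min
  tt <- sort(unique(c(0, tp, tf)))
  traj <- pk_simulate(p_hat, observations$C1_0, tt)
  pred_pla <- traj$C1[match(tp, tt)]
  pred_myo <- myocardial_concentration(traj, ratios)[match(tf, tt)]
  r2 <- goodness_of_fit(observations, pred_pla, pred_myo, Rmyo)

  structure(list(k = k_hat, Rmyo = Rmyo, fval = best$value,
                 r_squared = r2,
                 converged = identical(best$convergence, 0L) ||
                   best$convergence == 0,
                 n_iterations = unname(best$counts["function"]),
                 n_starts = n_starts, best_start = best$start,
                 seed = seed, k_max = k_max, starts = starts_log,
                 identifiability = ident,
                 observations = observations, volumes = volumes,
                 ratios = ratios, params = p_hat),
            class = "pk3_fit")
}

#' Pooled coefficient of determination
#'
#' R^2 between observations and model predictions with both streams
#' pooled in concentration units: the fluorescence observations are
#' converted with Rmyo, residual and total sums of squares are taken
#' over the concatenated vector, and the total is about the pooled
#' mean.
#'
#' @param observations An [observation_set()].
#' @param pred_plasma Model plasma concentrations at the plasma
#'   observation times.
#' @param pred_myo Model myocardial (mixture) concentrations at the
#'   fluorescence observation times.
#' @param Rmyo Conversion constant.
#' @return R^2 (dimensionless, <= 1).
#' @export
goodness_of_fit <- function(observations, pred_plasma, pred_myo, Rmyo) {
  stopifnot(inherits(observations, "observation_set"))
  if (length(pred_plasma) != nrow(observations$plasma) ||
      length(pred_myo) != nrow(observations$fluorescence))
    stop("prediction lengths do not match the observation streams",
         call. = FALSE)
  obs <- c(observations$plasma$value,
           fluorescence_to_concentration(observations$fluorescence$value,
                                         Rmyo))
  pred <- c(pred_plasma, pred_myo)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("observations have zero variance; R^2 undefined", call. = FALSE)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Peak of the interstitial concentration curve
#'
#' Locates the maximum of C2(t) on a refined grid (default 0.1 min) and
#' reports it together with its ratio to the initial plasma
#' concentration.  A peak on the last grid point is flagged: the
#' simulated window may not cover the true maximum.
#'
#' @param trajectory A `pk_trajectory` (from [pk_simulate()]); the peak
#'   is re-located on a refined grid over the same time span using the
#'   stored parameters.  A `pk3_fit` is also accepted (its fitted
#'   parameters are simulated over the observation span).
#' @param resolution Grid step in minutes (<= 0.1 recommended).
#' @return List with `peak_time_min`, `peak_concentration` (ug/mL),
#'   `ratio_to_C1_0_pct`, and `at_boundary` (logical flag).
#' @export
summarize_interstitial <- function(trajectory, resolution = 0.1) {
  check_number(resolution, "resolution", 0, strict_lower = TRUE)
  if (inherits(trajectory, "pk3_fit")) {
    params <- trajectory$params
    C1_0 <- trajectory$observations$C1_0
    tmax <- max(trajectory$observations$plasma$time_min,
                trajectory$observations$fluorescence$time_min)
  } else {
    params <- attr(trajectory, "params")
    C1_0 <- attr(trajectory, "C1_0")
    if (is.null(params))
      stop("`trajectory` must come from pk_simulate() or be a pk3_fit",
           call. = FALSE)
    tmax <- max(trajectory$time_min)
  }
  grid <- seq(0, tmax, by = resolution)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  traj <- pk_simulate(params, C1_0, grid)
  i <- which.max(traj$C2)
  at_boundary <- i == length(grid) || i == 1L
  if (i == length(grid))
    warning("interstitial peak lies on the grid boundary; ",
            "extend the simulated window", call. = FALSE)
  list(peak_time_min = grid[i],
       peak_concentration = traj$C2[i],
       ratio_to_C1_0_pct = if (C1_0 > 0) 100 * traj$C2[i] / C1_0 else NA_real_,
       at_boundary = at_boundary)
}
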