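#' Compartment model parameters
#'
#' Combines the three compartment volumes with the five first-order
#' rate constants of the mammillary-catenary chain
#' plasma (1) <-> interstitium (2) <-> cell (3), with elimination
#' `k10` out of plasma.  All rates are per minute and act on
#' concentrations; the governing equations on amounts `A_i = V_i C_i`
#' are linear with constant coefficients.
#'
#' @param volumes A [compartment_volumes()] object (or named numeric
#'   `V1_ml`, `V2_ml`, `V3_ml`).
#' @param k10 Elimination rate from plasma, 1/min, >= 0.
#' @param k12,k21 Plasma <-> interstitium transfer rates, 1/min, >= 0.
#' @param k23,k32 Interstitium <-> cell transfer rates, 1/min, >= 0.
#' @return Object of class `compartment_params`.
#' @examples
#' compartment_params(compartment_volumes(394, 251, 970),
#'                    k10 = 0.045, k12 = 0.145, k21 = 0.27,
#'                    k23 = 0.43, k32 = 0.36)
#' @export
compartment_params <- function(volumes, k10, k12, k21, k23, k32) {
  if (!inherits(volumes, "compartment_volumes"))
    volumes <- compartment_volumes(volumes[["V1_ml"]], volumes[["V2_ml"]],
                                   volumes[["V3_ml"]])
  for (nm in c("k10", "k12", "k21", "k23", "k32"))
    check_number(get(nm), nm, 0)
  structure(list(volumes = volumes,
                 k = c(k10 = unname(k10), k12 = unname(k12),
                       k21 = unname(k21), k23 = unname(k23),
                       k32 = unname(k32))),
            class = "compartment_params")
}

#' @export
print.compartment_params <- function(x, digits = 4, ...) {
  cat("Three-compartment model parameters\n")
  print(signif(x$k, digits))
  print(x$volumes)
  invisible(x)
}

#' Rate matrix of the amount-space linear system
#'
#' Returns the 3x3 matrix M such that `dA/dt = M A` for the drug
#' amounts `A = (V1 C1, V2 C2, V3 C3)`.  Column sums are `-k10` for the
#' plasma column and 0 otherwise, so total drug amount is conserved
#' when `k10 = 0`.
#'
#' @param params A [compartment_params()] object, or a named numeric of
#'   the five rate constants.
#' @return 3x3 numeric matrix.
#' @examples
#' rate_matrix(c(k10 = 0.1, k12 = 0.2, k21 = 0.05, k23 = 0.03, k32 = 0.01))
#' @export
rate_matrix <- function(params) {
  k <- if (inherits(params, "compartment_params")) params$k else params
  k <- k[c("k10", "k12", "k21", "k23", "k32")]
  if (anyNA(k) || any(k < 0))
    stop("rate constants must be named, numeric and nonnegative",
         call. = FALSE)
  matrix(c(-(k[["k10"]] + k[["k12"]]), k[["k12"]], 0,
           k[["k21"]], -(k[["k21"]] + k[["k23"]]), k[["k23"]],
           0, k[["k32"]], -k[["k32"]]),
         nrow = 3, ncol = 3,
         dimnames = list(paste0("A", 1:3), paste0("A", 1:3)))
}

# exp(M t) a0 evaluated at all times, vectorised via eigendecomposition;
# falls back to a Pade matrix exponential (Matrix::expm) per time point
# when the eigenbasis is numerically unreliable (defective/ill-conditioned).
expm_apply <- function(M, a0, times) {
  e <- eigen(M)
  ok <- FALSE
  co <- tryCatch(solve(e$vectors, a0), error = function(err) NULL)
  if (!is.null(co)) {
    recon <- e$vectors %*% (e$values * solve(e$vectors))
    ok <- max(abs(Re(recon) - M)) <= 1e-9 * max(abs(M), 1) &&
      max(abs(Im(recon))) <= 1e-9 * max(abs(M), 1)
  }
  if (ok) {
    E <- exp(outer(e$values, times))          # 3 x T, possibly complex
    A <- Re(e$vectors %*% (E * co))
  } else {
    A <- vapply(times, function(t)
      as.numeric(Matrix::expm(Matrix::Matrix(M * t)) %*% a0),
      numeric(3))
  }
  A
}

#' Simulate compartment concentrations after a bolus
#'
#' Exact solution of the linear three-compartment system for a bolus at
#' t = 0: initial amounts `(V1 * C1_0, 0, 0)`, propagated with the
#' matrix exponential of [rate_matrix()] and converted back to
#' concentrations.  No numerical integration is involved.
#'
#' @param params A [compartment_params()] object.
#' @param C1_0 Initial plasma concentration, ug/mL, >= 0.
#' @param times Strictly increasing sample times in minutes, starting
#'   at 0.
#' @return A data frame of class `pk_trajectory` with columns
#'   `time_min`, `C1`, `C2`, `C3` (ug/mL).  The generating `params` and
#'   `C1_0` are kept as attributes.
#' @examples
#' p <- compartment_params(compartment_volumes(394, 251, 970),
#'                         0.045, 0.145, 0.27, 0.43, 0.36)
#' traj <- pk_simulate(p, C1_0 = 59.01, times = seq(0, 85, 5))
#' head(traj)
#' @export
pk_simulate <- function(params, C1_0, times) {
  stopifnot(inherits(params, "compartment_params"))
  check_number(C1_0, "C1_0", 0)
  check_times(times, require_zero_start = TRUE)
  M <- rate_matrix(params)
  V <- unclass(params$volumes)
  A <- expm_apply(M, c(V[[1]] * C1_0, 0, 0), times)
  C <- A / V                    # rows recycle over columns (3 x T)
  # clamp roundoff-level negatives from the exponential
  C[C < 0 & C > -1e-9 * max(C1_0, 1)] <- 0
  out <- data.frame(time_min = times, C1 = C[1, ], C2 = C[2, ], C3 = C[3, ])
  structure(out, class = c("pk_trajectory", "data.frame"),
            params = params, C1_0 = C1_0)
}

#' Myocardial concentration as a fluorescence-weighted mixture
#'
#' `Cmyo(t) = R1 C1(t) + R2 C2(t) + R3 C3(t)`: the tissue fluorescence
#' observable is the volume-ratio-weighted sum of the compartment
#' concentrations.
#'
#' @param trajectory A `pk_trajectory` (or data frame with `C1`, `C2`,
#'   `C3` columns).
#' @param ratios A [volume_ratios()] object (weights summing to 1).
#' @return Numeric vector of Cmyo, ug/mL, aligned with the trajectory.
#' @export
myocardial_concentration <- function(trajectory, ratios) {
  r <- unclass(ratios)
  if (length(r) != 3L || abs(sum(r) - 1) > 1e-8)
    stop("`ratios` must be three weights summing to 1", call. = FALSE)
  if (!all(c("C1", "C2", "C3") %in% names(trajectory)))
    stop("`trajectory` must have columns C1, C2, C3", call. = FALSE)
  n <- lengths(trajectory[c("C1", "C2", "C3")])
  if (length(unique(n)) != 1L)
    stop("concentration columns have mismatched lengths", call. = FALSE)
  r[[1]] * trajectory$C1 + r[[2]] * trajectory$C2 + r[[3]] * trajectory$C3
}

#' Convert relative fluorescence to absolute concentration
#'
#' `C'myo = Rmyo * Mmyo`, where Rmyo is the conversion constant in
#' ug/(mL * counts).
#'
#' @param Mmyo Fluorescence series, relative counts.
#' @param Rmyo Conversion constant, > 0.
#' @return Concentration series, ug/mL.
#' @examples
#' fluorescence_to_concentration(0.025, 189) # 4.725
#' @export
fluorescence_to_concentration <- function(Mmyo, Rmyo) {
  check_number(Rmyo, "Rmyo", 0, strict_lower = TRUE)
  if (!is.numeric(Mmyo)) stop_bad_arg("Mmyo", "must be numeric")
  Rmyo * Mmyo
}

#' Total drug amount over time (mass-balance diagnostic)
#'
#' `V1 C1 + V2 C2 + V3 C3` in micrograms at each time point.  Constant
#' when `k10 = 0`; strictly nonincreasing otherwise.
#'
#' @param trajectory A `pk_trajectory`.
#' @param volumes A [compartment_volumes()] object; defaults to the
#'   volumes stored in the trajectory.
#' @return Numeric vector, ug.
#' @export
total_amount <- function(trajectory, volumes = NULL) {
  if (is.null(volumes)) {
    p <- attr(trajectory, "params")
    if (is.null(p)) stop("supply `volumes` for a bare data frame",
                         call. = FALSE)
    volumes <- p$volumes
  }
  v <- unclass(volumes)
  v[[1]] * trajectory$C1 + v[[2]] * trajectory$C2 + v[[3]] * trajectory$C3
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf("Compartment trajectory: %d time points, %g-%g min\n",
              nrow(x), min(x$time_min), max(x$time_min)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.pk_trajectory <- function(x, ratios = NULL, log = "", ...) {
  cols <- c(C1 = "red3", C2 = "darkorange2", C3 = "steelblue3")
  graphics::matplot(x$time_min, cbind(x$C1, x$C2, x$C3), type = "l",
                    lty = 1, col = cols, lwd = 2, log = log,
                    xlab = "time (min)",
                    ylab = expression(paste("concentration (", mu,
                                            "g/mL)")), ...)
  leg <- c("plasma", "interstitial", "cell")
  lcol <- cols
  if (!is.null(ratios)) {
    cmyo <- myocardial_concentration(x, ratios)
    graphics::lines(x$time_min, cmyo, col = "black", lwd = 2)
    leg <- c(leg, "myocardium (mixture)")
    lcol <- c(cols, "black")
  }
  graphics::legend("topright", legend = leg, col = lcol, lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}
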