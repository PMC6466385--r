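#' @export
print.pk3_fit <- function(x, digits = 4, ...) {
  cat("Three-compartment fit (multi-start bound-constrained least squares)\n")
  cat("Rate constants (1/min):\n")
  print(signif(x$k, digits))
  cat(sprintf("Rmyo = %.4g ug/(mL*counts)   fval = %.4g (ug/mL)^2   R^2 = %.4f\n",
              x$Rmyo, x$fval, x$r_squared))
  if (!all(x$identifiability))
    cat("Weakly identified (flat curvature or at bound): ",
        paste(names(x$k)[!x$identifiability], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Summary of a three-compartment fit
#'
#' @param object A `pk3_fit`.
#' @param ... Unused.
#' @return A `summary.pk3_fit` list: estimates, objective, pooled R^2,
#'   convergence and per-start diagnostics, identifiability flags, and
#'   the interstitial peak summary.
#' @export
summary.pk3_fit <- function(object, ...) {
  peak <- summarize_interstitial(object)
  structure(list(k = object$k, Rmyo = object$Rmyo, fval = object$fval,
                 r_squared = object$r_squared,
                 converged = object$converged,
                 n_iterations = object$n_iterations,
                 n_starts = object$n_starts,
                 best_start = object$best_start,
                 n_failed_starts = sum(is.na(object$starts$fval)),
                 identifiability = object$identifiability,
                 interstitial_peak = peak,
                 volumes = object$volumes, ratios = object$ratios),
            class = "summary.pk3_fit")
}

#' @export
print.summary.pk3_fit <- function(x, digits = 4, ...) {
  cat("Three-compartment pharmacokinetic fit\n\n")
  cat("Rate constants (1/min):\n")
  print(signif(x$k, digits))
  cat(sprintf("\nRmyo:  %.4g ug/(mL*counts)\nfval:  %.4g (ug/mL)^2\nR^2:   %.4f\n",
              x$Rmyo, x$fval, x$r_squared))
  cat(sprintf("Converged: %s after %d objective evaluations (best of %d starts, %d failed)\n",
              x$converged, x$n_iterations, x$n_starts, x$n_failed_starts))
  if (!all(x$identifiability))
    cat("Weakly identified: ",
        paste(names(x$k)[!x$identifiability], collapse = ", "), "\n",
        sep = "")
  cat(sprintf("\nInterstitial peak: %.3g ug/mL at %.1f min (%.1f%% of C1(0))\n",
              x$interstitial_peak$peak_concentration,
              x$interstitial_peak$peak_time_min,
              x$interstitial_peak$ratio_to_C1_0_pct))
  invisible(x)
}

#' @export
coef.pk3_fit <- function(object, ...) {
  c(object$k, Rmyo = object$Rmyo)
}

#' Predict compartment or observable concentrations from a fit
#'
#' @param object A `pk3_fit`.
#' @param times Minutes at which to evaluate; defaults to a 0.5-min
#'   grid over the observation span.  Must start at 0 (bolus).
#' @param type `"compartments"` for the full trajectory data frame
#'   (with a `Cmyo` column appended), `"plasma"` for C1,
#'   `"myocardial"` for the mixture Cmyo, `"fluorescence"` for
#'   Cmyo / Rmyo (the expected probe reading).
#' @param ... Unused.
#' @return Data frame or numeric vector according to `type`.
#' @export
predict.pk3_fit <- function(object, times = NULL,
                            type = c("compartments", "plasma",
                                     "myocardial", "fluorescence"), ...) {
  type <- match.arg(type)
  if (is.null(times)) {
    tmax <- max(object$observations$plasma$time_min,
                object$observations$fluorescence$time_min)
    times <- seq(0, tmax, by = 0.5)
  }
  traj <- pk_simulate(object$params, object$observations$C1_0, times)
  switch(type,
         compartments = {
           traj$Cmyo <- myocardial_concentration(traj, object$ratios)
           traj
         },
         plasma = traj$C1,
         myocardial = myocardial_concentration(traj, object$ratios),
         fluorescence =
           myocardial_concentration(traj, object$ratios) / object$Rmyo)
}

#' @export
fitted.pk3_fit <- function(object, ...) {
  obs <- object$observations
  tt <- sort(unique(c(0, obs$plasma$time_min, obs$fluorescence$time_min)))
  traj <- pk_simulate(object$params, obs$C1_0, tt)
  list(plasma = traj$C1[match(obs$plasma$time_min, tt)],
       myocardial = myocardial_concentration(traj, object$ratios)[
         match(obs$fluorescence$time_min, tt)])
}

#' Residuals of a three-compartment fit
#'
#' Observed minus predicted, in concentration units for both streams
#' (fluorescence converted with the fitted Rmyo).
#'
#' @param object A `pk3_fit`.
#' @param type `"pooled"` (single vector with a `stream` attribute) or
#'   `"list"` (separate plasma / myocardial vectors).
#' @param ... Unused.
#' @export
residuals.pk3_fit <- function(object, type = c("pooled", "list"), ...) {
  type <- match.arg(type)
  f <- fitted(object)
  obs <- object$observations
  r_pla <- obs$plasma$value - f$plasma
  r_myo <- fluorescence_to_concentration(obs$fluorescence$value,
                                         object$Rmyo) - f$myocardial
  if (type == "list") return(list(plasma = r_pla, myocardial = r_myo))
  structure(c(r_pla, r_myo),
            stream = rep(c("plasma", "myocardial"),
                         c(length(r_pla), length(r_myo))))
}

#' Simulate new observation sets from a fitted model
#'
#' Parametric resampling: model predictions at the original sampling
#' times with proportional Gaussian noise at the requested coefficient
#' of variation (0 reproduces the noise-free predictions).
#'
#' @param object A `pk3_fit`.
#' @param nsim Number of replicate observation sets.
#' @param seed Integer seed.
#' @param cv Proportional noise coefficient of variation.
#' @param ... Unused.
#' @return List of `nsim` [observation_set()] objects.
#' @export
simulate.pk3_fit <- function(object, nsim = 1, seed = NULL, cv = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$observations
  f <- fitted(object)
  mu_pla <- f$plasma
  mu_flu <- f$myocardial / object$Rmyo
  replicate(nsim, {
    pla <- pmax(0, mu_pla * (1 + cv * stats::rnorm(length(mu_pla))))
    flu <- pmax(0, mu_flu * (1 + cv * stats::rnorm(length(mu_flu))))
    observation_set(
      data.frame(time_min = obs$plasma$time_min, value = pla),
      data.frame(time_min = obs$fluorescence$time_min, value = flu),
      C1_0 = obs$C1_0)
  }, simplify = FALSE)
}

#' Plot a three-compartment fit
#'
#' Fitted compartment curves with the observations overlaid (plasma as
#' points, converted fluorescence as filled squares), echoing the
#' standard concentration-time figure of compartmental analyses.
#'
#' @param x A `pk3_fit`.
#' @param resolution Curve grid step, minutes.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pk3_fit <- function(x, resolution = 0.5, ...) {
  obs <- x$observations
  tmax <- max(obs$plasma$time_min, obs$fluorescence$time_min)
  traj <- pk_simulate(x$params, obs$C1_0, seq(0, tmax, by = resolution))
  plot(traj, ratios = x$ratios, ...)
  graphics::points(obs$plasma$time_min, obs$plasma$value,
                   pch = 1, col = "red3")
  graphics::points(obs$fluorescence$time_min,
                   fluorescence_to_concentration(obs$fluorescence$value,
                                                 x$Rmyo),
                   pch = 15, col = "black")
  invisible(x)
}
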