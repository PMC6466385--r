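# shared fixtures: the canine study configuration and small helpers

canine_fixture <- function() {
  hist <- canine_histology()
  areas <- area_ratios(hist)
  ratios <- volume_ratios(areas)
  dv <- derive_volumes(canine_subject(), areas)
  list(hist = hist, areas = areas, ratios = ratios,
       volumes = dv$volumes, C1_0 = dv$C1_0)
}

default_k <- c(k10 = 0.045, k12 = 0.145, k21 = 0.27, k23 = 0.43,
               k32 = 0.36)

canine_params <- function(k = default_k) {
  fx <- canine_fixture()
  compartment_params(fx$volumes, k[["k10"]], k[["k12"]], k[["k21"]],
                     k[["k23"]], k[["k32"]])
}

# independent oracle: adaptive numerical integration of the
# concentration-space ODEs at tight tolerance (never used by the package
# itself, which solves the system in closed form)
ode_oracle <- function(params, C1_0, times) {
  V <- unclass(params$volumes)
  k <- params$k
  deriv <- function(t, C, p) {
    dC1 <- (-(k[["k10"]] + k[["k12"]]) * V[[1]] * C[1] +
              k[["k21"]] * V[[2]] * C[2]) / V[[1]]
    dC2 <- (k[["k12"]] * V[[1]] * C[1] -
              (k[["k21"]] + k[["k23"]]) * V[[2]] * C[2] +
              k[["k32"]] * V[[3]] * C[3]) / V[[2]]
    dC3 <- (k[["k23"]] * V[[2]] * C[2] - k[["k32"]] * V[[3]] * C[3]) /
      V[[3]]
    list(c(dC1, dC2, dC3))
  }
  out <- deSolve::ode(y = c(C1_0, 0, 0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-12)
  list(C1 = out[, 2], C2 = out[, 3], C3 = out[, 4])
}

# random nonnegative rate-constant draws on a log-uniform scale
random_k <- function(n, lo = 1e-4, hi = 1) {
  matrix(10^runif(5 * n, log10(lo), log10(hi)), ncol = 5,
         dimnames = list(NULL, names(default_k)))
}

# noise-free observation set on given schedules from the canine truth
noise_free_obs <- function(plasma_times = c(0, 5, 10, 15, 20, 30, 40, 50,
                                            60, 70, 75, 85),
                           fluor_times = c(0, 10, 40),
                           k = default_k, Rmyo = 189) {
  d <- study_design(plasma_times_min = plasma_times,
                    fluorescence_times_min = fluor_times,
                    noise_model = "none", true_k = k, true_Rmyo = Rmyo)
  generate_observations(d)
}
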