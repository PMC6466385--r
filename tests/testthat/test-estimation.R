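test_that("Rmyo is fixed by the t = 0 fluorescence match", {
  expect_equal(compute_rmyo(59.01, 0.08, 0.024979), 189, tolerance = 1e-4)
  expect_equal(compute_rmyo(59.01, 0.08, 0.08 * 59.01), 1)
  expect_equal(compute_rmyo(59.01, 0.08, 0.0472), 100, tolerance = 2e-4)
  expect_error(compute_rmyo(59.01, 0.08, 0), "reference time")
  expect_error(compute_rmyo(59.01, 0.08, -0.01), "reference time")
})

test_that("observation sets validate, sort and count their points", {
  pla <- data.frame(time_min = c(0, 10, 5), value = c(59, 30, 40))
  flu <- data.frame(time_min = c(0, 10), value = c(0.025, 0.02))
  obs <- observation_set(pla, flu, C1_0 = 59)
  expect_equal(obs$plasma$time_min, c(0, 5, 10))
  expect_equal(obs$plasma$value, c(59, 40, 30))
  expect_error(observation_set(pla[1:2, ], flu, 59), "at least 2")
  expect_error(observation_set(pla, flu[1, , drop = FALSE], 59),
               "at least 1")
  dup <- data.frame(time_min = c(0, 5, 5), value = c(59, 40, 41))
  expect_error(observation_set(dup, flu, 59), "increasing")
})

test_that("fval is zero at the generating parameters and grows quadratically", {
  sim <- noise_free_obs()
  obs <- sim$observations
  tr <- sim$truth
  expect_lt(pk_objective(tr$k, obs, tr$volumes, tr$ratios, tr$Rmyo),
            1e-12)

  # a single plasma point off by delta adds delta^2 / Npla
  delta <- 0.7
  obs2 <- obs
  obs2$plasma$value[4] <- obs2$plasma$value[4] + delta
  expect_equal(pk_objective(tr$k, obs2, tr$volumes, tr$ratios, tr$Rmyo),
               delta^2 / nrow(obs$plasma), tolerance = 1e-9)

  # any perturbation of the parameters raises fval on noise-free data
  set.seed(9)
  dense <- noise_free_obs(plasma_times = 0:85, fluor_times = 0:85)
  for (i in 1:10) {
    kp <- tr$k * (1 + 0.1 * rnorm(5))
    kp <- pmax(kp, 0)
    expect_gt(pk_objective(kp, dense$observations, tr$volumes, tr$ratios,
                           tr$Rmyo),
              pk_objective(tr$k, dense$observations, tr$volumes,
                           tr$ratios, tr$Rmyo))
  }
})

test_that("fval does not depend on observation row order", {
  sim <- generate_observations(study_design(seed = 12))
  obs <- sim$observations
  perm <- sample(nrow(obs$plasma))
  obs_shuffled <- observation_set(obs$plasma[perm, ],
                                  obs$fluorescence[c(2, 3, 1), ],
                                  obs$C1_0)
  k <- c(k10 = 0.1, k12 = 0.1, k21 = 0.1, k23 = 0.1, k32 = 0.1)
  expect_identical(
    pk_objective(k, obs, sim$truth$volumes, sim$truth$ratios, 189),
    pk_objective(k, obs_shuffled, sim$truth$volumes, sim$truth$ratios,
                 189))
})

test_that("a monoexponential decay recovers k10 with other rates at zero", {
  fx <- canine_fixture()
  k <- c(k10 = 0.3, k12 = 0, k21 = 0, k23 = 0, k32 = 0)
  sim <- noise_free_obs(k = k)
  fit <- fit_rate_constants(sim$observations, fx$volumes, fx$ratios,
                            n_starts = 6, seed = 2)
  expect_equal(unname(fit$k[["k10"]]), 0.3, tolerance = 1e-4)
  # the plasma->interstitium rate must collapse to the lower bound; the
  # downstream rates are then unidentified (flat directions)
  expect_lt(fit$k[["k12"]], 1e-4)
  expect_lt(fit$fval, 1e-10)
  expect_true(fit$converged)
})

test_that("the winning start never ends worse than it began", {
  sim <- generate_observations(study_design(seed = 5))
  fit <- fit_rate_constants(sim$observations, sim$truth$volumes,
                            sim$truth$ratios, n_starts = 4, seed = 5)
  log <- fit$starts
  expect_true(all(log$fval <= log$fval_init + 1e-12, na.rm = TRUE))
  expect_equal(fit$fval, min(log$fval, na.rm = TRUE))
})

test_that("pooled R^2 matches its definition", {
  pla <- data.frame(time_min = c(0, 5, 10), value = c(10, 6, 4))
  flu <- data.frame(time_min = c(0, 10), value = c(0.05, 0.03))
  obs <- observation_set(pla, flu, C1_0 = 10)
  Rmyo <- 100
  # perfect fit
  expect_equal(goodness_of_fit(obs, c(10, 6, 4), c(5, 3), Rmyo), 1)
  # constant prediction at the pooled mean scores zero
  m <- mean(c(10, 6, 4, 5, 3))
  expect_equal(goodness_of_fit(obs, rep(m, 3), rep(m, 2), Rmyo), 0)
  # hand-computed residuals
  pred_p <- c(9, 6.5, 4); pred_m <- c(5.2, 2.9)
  ss_res <- (10 - 9)^2 + (6 - 6.5)^2 + 0 + (5 - 5.2)^2 + (3 - 2.9)^2
  ss_tot <- sum((c(10, 6, 4, 5, 3) - m)^2)
  expect_equal(goodness_of_fit(obs, pred_p, pred_m, Rmyo),
               1 - ss_res / ss_tot)
  expect_error(goodness_of_fit(obs, c(10, 6), c(5, 3), Rmyo), "lengths")
  const <- observation_set(data.frame(time_min = c(0, 5, 10),
                                      value = c(2, 2, 2)),
                           data.frame(time_min = c(0, 10),
                                      value = c(0.02, 0.02)),
                           C1_0 = 2)
  expect_error(goodness_of_fit(const, rep(2, 3), rep(2, 2), 100),
               "variance")
})

test_that("the interstitial peak is located on a refined grid", {
  fx <- canine_fixture()
  p <- canine_params()
  tr <- pk_simulate(p, fx$C1_0, seq(0, 85, by = 5))
  s <- summarize_interstitial(tr, resolution = 0.1)
  # brute-force oracle on a much finer grid
  fine <- pk_simulate(p, fx$C1_0, seq(0, 85, by = 0.01))
  i <- which.max(fine$C2)
  expect_equal(s$peak_time_min, fine$time_min[i], tolerance = 0.1)
  expect_equal(s$peak_concentration, fine$C2[i], tolerance = 1e-4)
  expect_equal(s$ratio_to_C1_0_pct, 100 * fine$C2[i] / fx$C1_0,
               tolerance = 1e-4)
  expect_false(s$at_boundary)

  # with no uptake into the interstitium C2 stays at zero: boundary case
  p0 <- compartment_params(fx$volumes, 0.1, 0, 0, 0, 0)
  tr0 <- pk_simulate(p0, fx$C1_0, seq(0, 20, by = 1))
  s0 <- summarize_interstitial(tr0, resolution = 0.5)
  expect_equal(s0$peak_time_min, 0)
  expect_equal(s0$peak_concentration, 0)
  expect_true(s0$at_boundary)
})

test_that("fit methods expose the model the classic way", {
  sim <- generate_observations(study_design(seed = 3))
  fit <- fit_rate_constants(sim$observations, sim$truth$volumes,
                            sim$truth$ratios, n_starts = 4, seed = 3)
  expect_s3_class(fit, "pk3_fit")
  expect_named(coef(fit), c("k10", "k12", "k21", "k23", "k32", "Rmyo"))
  expect_output(print(fit), "Rate constants")
  expect_output(print(summary(fit)), "Interstitial peak")

  pr <- predict(fit, times = c(0, 10, 40))
  expect_named(pr, c("time_min", "C1", "C2", "C3", "Cmyo"))
  expect_equal(pr$Cmyo,
               myocardial_concentration(pr, fit$ratios))
  expect_equal(predict(fit, times = c(0, 10, 40), type = "fluorescence"),
               pr$Cmyo / fit$Rmyo)

  res <- residuals(fit)
  f <- fitted(fit)
  expect_length(res, nrow(sim$observations$plasma) +
                  nrow(sim$observations$fluorescence))
  expect_equal(unname(res[1:12]),
               sim$observations$plasma$value - f$plasma)

  sims <- simulate(fit, nsim = 2, seed = 1, cv = 0)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$plasma$value, f$plasma)

  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(tf)
})
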