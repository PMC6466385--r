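test_that("rate matrix transcribes the amount-space system", {
  z <- c(k10 = 0, k12 = 0, k21 = 0, k23 = 0, k32 = 0)
  expect_equal(unname(rate_matrix(z)), matrix(0, 3, 3))

  k <- c(k10 = 0.1, k12 = 0.2, k21 = 0.05, k23 = 0.03, k32 = 0.01)
  M <- rate_matrix(k)
  expect_equal(unname(M),
               matrix(c(-0.3, 0.2, 0,
                        0.05, -0.08, 0.03,
                        0, 0.01, -0.01), 3, 3))
  # column sums: -k10 for plasma, 0 for the others
  expect_equal(unname(colSums(M)), c(-0.1, 0, 0))
  k0 <- k; k0[["k10"]] <- 0
  expect_equal(unname(colSums(rate_matrix(k0))), c(0, 0, 0))
  expect_error(rate_matrix(c(k10 = -1, k12 = 0, k21 = 0, k23 = 0,
                             k32 = 0)), "nonnegative")
})

test_that("degenerate kinetics have their closed-form solutions", {
  fx <- canine_fixture()
  tt <- seq(0, 100, by = 5)
  # frozen system: nothing moves
  p0 <- compartment_params(fx$volumes, 0, 0, 0, 0, 0)
  tr <- pk_simulate(p0, 10, tt)
  expect_equal(tr$C1, rep(10, length(tt)))
  expect_equal(tr$C2, rep(0, length(tt)))
  expect_equal(tr$C3, rep(0, length(tt)))
  # elimination only: monoexponential decay
  p1 <- compartment_params(fx$volumes, 0.2, 0, 0, 0, 0)
  tr1 <- pk_simulate(p1, 10, tt)
  expect_equal(tr1$C1, 10 * exp(-0.2 * tt), tolerance = 1e-10)
})

test_that("exact solution matches adaptive numerical integration", {
  set.seed(101)
  ks <- random_k(8)
  tt <- seq(0, 120, length.out = 25)
  fx <- canine_fixture()
  for (i in seq_len(nrow(ks))) {
    p <- compartment_params(fx$volumes, ks[i, 1], ks[i, 2], ks[i, 3],
                            ks[i, 4], ks[i, 5])
    tr <- pk_simulate(p, fx$C1_0, tt)
    ref <- ode_oracle(p, fx$C1_0, tt)
    scale <- max(fx$C1_0, 1)
    expect_equal(tr$C1 / scale, ref$C1 / scale, tolerance = 1e-6)
    expect_equal(tr$C2 / scale, ref$C2 / scale, tolerance = 1e-6)
    expect_equal(tr$C3 / scale, ref$C3 / scale, tolerance = 1e-6)
  }
})

test_that("with the cell loop closed, C1 is the two-compartment biexponential", {
  fx <- canine_fixture()
  k10 <- 0.05; k12 <- 0.2; k21 <- 0.08
  p <- compartment_params(fx$volumes, k10, k12, k21, 0, 0)
  tt <- seq(0, 200, by = 2)
  tr <- pk_simulate(p, 50, tt)
  # classical bolus biexponential: alpha, beta are roots of
  # s^2 + (k10+k12+k21) s + k10 k21 = 0
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  c1 <- 50 * ((alpha - k21) * exp(-alpha * tt) -
                (beta - k21) * exp(-beta * tt)) / (alpha - beta)
  expect_equal(tr$C1, c1, tolerance = 1e-8)
  expect_equal(tr$C3, rep(0, length(tt)))
})

test_that("mass is conserved without elimination and decays with it", {
  set.seed(33)
  fx <- canine_fixture()
  tt <- seq(0, 120, length.out = 40)
  for (i in 1:10) {
    k <- random_k(1)[1, ]
    k[["k10"]] <- 0
    p <- compartment_params(fx$volumes, 0, k[["k12"]], k[["k21"]],
                            k[["k23"]], k[["k32"]])
    amt <- total_amount(pk_simulate(p, fx$C1_0, tt))
    a0 <- unclass(fx$volumes)[[1]] * fx$C1_0
    expect_equal(amt, rep(a0, length(tt)), tolerance = 1e-8)
  }
  # with elimination the total amount is nonincreasing
  p <- canine_params()
  amt <- total_amount(pk_simulate(p, fx$C1_0, tt))
  expect_equal(amt[1], unclass(fx$volumes)[[1]] * fx$C1_0)
  expect_true(all(diff(amt) <= 1e-10))
})

test_that("concentrations stay nonnegative for any nonnegative rates", {
  set.seed(44)
  fx <- canine_fixture()
  tt <- c(0, 10^seq(-1, 5, length.out = 30))
  for (i in 1:10) {
    k <- random_k(1)[1, ]
    p <- compartment_params(fx$volumes, k[["k10"]], k[["k12"]],
                            k[["k21"]], k[["k23"]], k[["k32"]])
    tr <- pk_simulate(p, fx$C1_0, tt)
    expect_true(all(c(tr$C1, tr$C2, tr$C3) >= -1e-9))
  }
})

test_that("with elimination and non-degenerate exchange all pools drain", {
  # rates well away from zero keep the slowest eigenvalue fast enough
  # that t = 1e5 min is deep in the terminal phase
  set.seed(45)
  fx <- canine_fixture()
  tt <- c(0, 1, 1e5)
  for (i in 1:10) {
    k <- random_k(1, lo = 0.1, hi = 1)[1, ]
    p <- compartment_params(fx$volumes, k[["k10"]], k[["k12"]],
                            k[["k21"]], k[["k23"]], k[["k32"]])
    tr <- pk_simulate(p, fx$C1_0, tt)
    expect_lt(max(tr$C1[3], tr$C2[3], tr$C3[3]), 1e-6 * fx$C1_0)
  }
})

test_that("simulation rejects malformed time grids", {
  p <- canine_params()
  expect_error(pk_simulate(p, 10, c(0, 5, 3)), "increasing")
  expect_error(pk_simulate(p, 10, c(5, 10)), "start at 0")
  expect_error(pk_simulate(p, -1, c(0, 5)), "C1_0")
})

test_that("myocardial mixture weights the compartment concentrations", {
  r <- volume_ratios(6.77, 15.93, 61.7)
  tr <- data.frame(C1 = 23250 / 394, C2 = 0, C3 = 0)
  expect_equal(round(myocardial_concentration(tr, r), 2), 4.73)
  expect_equal(myocardial_concentration(tr, r),
               unclass(r)[[1]] * 23250 / 394)
  # equal concentrations pass through unchanged (weights sum to 1)
  tr2 <- data.frame(C1 = c(3, 7), C2 = c(3, 7), C3 = c(3, 7))
  expect_equal(myocardial_concentration(tr2, r), c(3, 7))
  r1 <- volume_ratios(1, 0, 0)
  expect_equal(myocardial_concentration(tr2, r1), tr2$C1)
  bad <- data.frame(C1 = 1:2, C2 = 1:2, C3 = 1:2)
  bad$C3 <- NULL
  expect_error(myocardial_concentration(bad, r), "C1, C2, C3")
})

test_that("fluorescence converts to concentration by a positive constant", {
  expect_equal(fluorescence_to_concentration(0.025, 189), 4.725)
  expect_equal(fluorescence_to_concentration(0, 189), 0)
  expect_equal(fluorescence_to_concentration(1, 189), 189)
  expect_equal(fluorescence_to_concentration(c(0.01, 0.02), 100),
               c(1, 2))
  expect_error(fluorescence_to_concentration(0.025, 0), "Rmyo")
  expect_error(fluorescence_to_concentration(0.025, -5), "Rmyo")
})
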