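test_that("integration matches isothermal closed forms", {
  # first-order: alpha = 1 - e^{-kt} (up to the alpha0 regularization)
  p1 <- kinetic_params(lnA1 = log(0.05), Ea1 = 0, n1 = 1)
  cur <- integrate_extent(p1, constant_profile(25), c(0, 10))
  expect_equal(cur$alpha[2], 0.393469, tolerance = 1e-5)
  # zero-order accumulates k*t piecewise over a step-hold profile;
  # Ea chosen so that k jumps 0.001 -> 0.01 across the step
  prof <- temperature_profile(c(0, 10), temp_C = c(20, 30),
                              interpolation = "step")
  Ea_r <- log(10) * R_GAS / (1 / 293.15 - 1 / 303.15)
  lnA_r <- log(0.001) + Ea_r / (R_GAS * 293.15)
  pz <- kinetic_params(lnA1 = lnA_r, Ea1 = Ea_r, n1 = 0)
  cur2 <- integrate_extent(pz, prof, c(0, 11), alpha0 = 0)
  expect_equal(cur2$alpha[2], 0.001 * 10 + 0.01 * 1, tolerance = 1e-9)
  # single-point grid: no elapsed time
  cur3 <- integrate_extent(p1, constant_profile(25), 0, alpha0 = 1e-8)
  expect_equal(cur3$alpha, 1e-8)
})

test_that("closed forms hold to 1e-6 absolute over 3-year horizons at 5/25/40 degC", {
  grid <- seq(0, 3 * 365.25, length.out = 40)
  for (Ta in c(5, 25, 40)) {
    k <- arrhenius_k(26, 8e4, Ta + 273.15)
    pf <- kinetic_params(lnA1 = 26, Ea1 = 8e4, n1 = 1)
    cf <- integrate_extent(pf, constant_profile(Ta), grid, alpha0 = 0)
    expect_lt(max(abs(cf$alpha - (1 - exp(-k * grid)))), 1e-6)
    kz <- arrhenius_k(30, 9e4, Ta + 273.15)
    pz <- kinetic_params(lnA1 = 30, Ea1 = 9e4, n1 = 0)
    cz <- integrate_extent(pz, constant_profile(Ta), grid, alpha0 = 0)
    expect_lt(max(abs(cz$alpha - pmin(kz * grid, 1))), 1e-6)
  }
})

test_that("adaptive integrator agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  # autocatalytic two-step over a fluctuating profile: no closed form
  p <- kinetic_params(lnA1 = 28, Ea1 = 8.5e4, n1 = 1.2, m1 = 0.6,
                      lnA2 = 33, Ea2 = 1.05e5, n2 = 1, m2 = 0, v = 0.55)
  prof <- temperature_profile(c(0, 30, 31, 60, 61, 200),
                              temp_C = c(5, 5, 35, 35, 5, 5))
  grid <- seq(0, 200, length.out = 21)
  cur <- integrate_extent(p, prof, grid)
  rhs <- function(t, y, parms) {
    Tk <- temperature_at(prof, t)
    r <- extent_rate(p, min(max(y[1], 0), 1), min(max(y[2], 0), 1), Tk)
    list(c(r$dalpha1, r$dalpha2))
  }
  sol <- deSolve::lsoda(c(1e-8, 1e-8), grid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  alpha_ref <- 0.55 * sol[, 2] + 0.45 * sol[, 3]
  expect_lt(max(abs(cur$alpha - alpha_ref)), 1e-6)
})

test_that("integration satisfies the semigroup property across the catalog", {
  prof <- temperature_profile(c(0, 50, 55, 120), temp_C = c(5, 5, 30, 8))
  pars <- list(
    kinetic_params(lnA1 = 30, Ea1 = 9e4, n1 = 0),
    kinetic_params(lnA1 = 26, Ea1 = 8e4, n1 = 1),
    kinetic_params(lnA1 = 27, Ea1 = 8.5e4, n1 = 1.7),
    kinetic_params(lnA1 = 28, Ea1 = 9e4, n1 = 1.2, m1 = 0.5),
    kinetic_params(lnA1 = 10, Ea1 = 3e4, n1 = 1, lnA2 = 32, Ea2 = 1e5,
                   n2 = 1, m2 = 0.3, v = 0.3))
  for (p in pars) {
    full <- integrate_extent(p, prof, c(0, 120))
    part1 <- integrate_extent(p, prof, c(0, 57))
    # restart both sub-extents from the intermediate state
    a1 <- part1$alpha1[2]; a2 <- part1$alpha2[2]
    r1 <- integrate_extent(kinetic_params(lnA1 = p[["lnA1"]], Ea1 = p[["Ea1"]],
                                          n1 = p[["n1"]], m1 = p[["m1"]], v = 1),
                           prof, c(57, 120), alpha0 = a1)
    r2 <- integrate_extent(kinetic_params(lnA1 = p[["lnA2"]], Ea1 = p[["Ea2"]],
                                          n1 = p[["n2"]], m1 = p[["m2"]], v = 1),
                           prof, c(57, 120), alpha0 = a2)
    spliced <- p[["v"]] * r1$alpha[2] + (1 - p[["v"]]) * r2$alpha[2]
    expect_lt(abs(full$alpha[2] - spliced), 1e-6)
  }
})

test_that("a constant profile reproduces the isothermal solution exactly", {
  p <- kinetic_params(lnA1 = 28, Ea1 = 9e4, n1 = 1.2, m1 = 0.5)
  grid <- seq(0, 365, length.out = 30)
  iso <- integrate_extent(p, constant_profile(25), grid)
  multi_knot <- temperature_profile(c(0, 100, 365), temp_C = c(25, 25, 25))
  flat <- integrate_extent(p, multi_knot, grid)
  expect_equal(flat$alpha, iso$alpha, tolerance = 1e-9)
})

test_that("separable one-step kinetics obey time-temperature superposition", {
  # under profile T(t), alpha(t) = isothermal alpha at tau = int k(T)ds / k_ref
  lnA <- 26; Ea <- 8e4
  prof <- temperature_profile(c(0, 20, 21, 40, 41, 100),
                              temp_C = c(5, 5, 30, 30, 5, 5))
  p <- kinetic_params(lnA1 = lnA, Ea1 = Ea, n1 = 1)
  cur <- integrate_extent(p, prof, c(0, 100), alpha0 = 0)
  tau <- equivalent_days(p, prof, t_end = 100, ref_temp_C = 5)
  k_ref <- arrhenius_k(lnA, Ea, 278.15)
  expect_equal(cur$alpha[2], 1 - exp(-k_ref * tau), tolerance = 1e-7)
})

test_that("alpha is monotone in time and in profile temperature", {
  p <- kinetic_params(lnA1 = 28, Ea1 = 9e4, n1 = 1.2, m1 = 0.4)
  grid <- seq(0, 400, length.out = 50)
  prof_lo <- temperature_profile(c(0, 200, 400), temp_C = c(5, 20, 10))
  prof_hi <- temperature_profile(c(0, 200, 400), temp_C = c(8, 23, 13))
  lo <- integrate_extent(p, prof_lo, grid)
  hi <- integrate_extent(p, prof_hi, grid)
  expect_true(all(diff(lo$alpha) >= -1e-12))
  expect_true(all(lo$alpha >= 0 & lo$alpha <= 1))
  expect_gt(hi$alpha[50], lo$alpha[50])
})

test_that("attribute mapping is linear in extent with the stated direction", {
  up <- attribute_transform(y0 = 0.5, span = 10, direction = 1,
                            name = "HMW", unit = "%")
  down <- attribute_transform(y0 = 100, span = 100, direction = -1)
  expect_equal(predict_attribute(0.2, up), 2.5)
  expect_equal(predict_attribute(0.2, down), 80)
  expect_equal(predict_attribute(0, down), 100)
  expect_error(attribute_transform(y0 = 1, span = 0), "span")
  # trajectory CSV export carries time/temperature/alpha/value
  p <- kinetic_params(lnA1 = log(0.01), Ea1 = 0, n1 = 1)
  cur <- predict_attribute(integrate_extent(p, constant_profile(5), c(0, 50, 100)), up)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(cur, tmp)
  back <- read.csv(tmp)
  expect_equal(back$value, cur$value)
  expect_equal(back$temperature_C, rep(5, 3))
})
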