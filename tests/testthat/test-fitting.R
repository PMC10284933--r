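test_that("information criteria follow the least-squares convention", {
  ic <- stabkin:::information_criteria(RSS = 0.3, N = 30, K = 3)
  expect_equal(ic$AIC, 30 * log(0.01) + 2 * 4)
  expect_equal(ic$AIC, -130.155, tolerance = 1e-4)
  expect_equal(ic$AICc, ic$AIC + 2 * 4 * 5 / (30 - 3 - 2))
  expect_equal(ic$BIC, 30 * log(0.01) + 4 * log(30))
  expect_gt(ic$AICc, ic$AIC)
})

test_that("noiseless first-order data are recovered almost exactly", {
  obs <- make_first_order_obs(lnA = 26, Ea = 8e4)
  fit <- fit_model(first_order_spec(), obs, n_starts = 4)
  expect_true(fit$converged)
  expect_lt(fit$RSS, 1e-8)
  # k(T) at each arm within 0.1% relative error
  for (Ta in c(5, 25, 40)) {
    k_true <- arrhenius_k(26, 8e4, Ta + 273.15)
    k_fit <- arrhenius_k(fit$params[["lnA1"]], fit$params[["Ea1"]], Ta + 273.15)
    expect_lt(abs(k_fit / k_true - 1), 1e-3)
  }
  # refusal when N cannot support K (AICc undefined)
  tiny <- obs[obs$time %in% unique(obs$time)[1:2] & obs$temp_K < 300, ]
  expect_error(fit_model(first_order_spec(), tiny), "AICc")
})

test_that("noiseless one-step catalog curves refit to 1e-3 relative accuracy", {
  cases <- list(
    list(spec = "zero-order", p = kinetic_params(lnA1 = 30, Ea1 = 9e4, n1 = 0)),
    list(spec = "first-order", p = kinetic_params(lnA1 = 26, Ea1 = 8e4, n1 = 1)),
    list(spec = "nth-order", p = kinetic_params(lnA1 = 30.5, Ea1 = 9.5e4, n1 = 1.8)))
  times <- c(0, 7.6, 15.2, 30.4, 60.9, 91.3, 182.6)
  for (cs in cases) {
    obs <- do.call(rbind, lapply(c(5, 25, 40), function(Ta) {
      cur <- integrate_extent(cs$p, constant_profile(Ta), times)
      data.frame(time = times, temp_K = Ta + 273.15, alpha = cur$alpha, C = 1)
    }))
    fit <- fit_model(default_model_catalog()[[cs$spec]], obs, n_starts = 4)
    for (nm in fit$spec$free)
      expect_lt(abs(fit$estimate[[nm]] / cs$p[[nm]] - 1), 1e-3,
                label = paste(cs$spec, nm))
  }
})

test_that("degenerate flat data fit a zero-rate zero-order model with RSS 0", {
  obs <- data.frame(time = rep(c(0, 30, 60, 90, 120, 150, 180), 3),
                    temp_K = rep(c(278.15, 298.15, 313.15), each = 7),
                    alpha = 0, C = 1)
  fit <- fit_model(default_model_catalog()[["zero-order"]], obs, n_starts = 2)
  expect_lt(fit$RSS, 1e-10)
  expect_lt(max(abs(fit$fitted)), 1e-4)
})

test_that("nested models never fit worse than their special cases", {
  obs <- make_first_order_obs(sigma = 0.01, seed = 11)
  f1 <- fit_model(first_order_spec(), obs, n_starts = 4)
  fn <- fit_model(default_model_catalog()[["nth-order"]], obs, n_starts = 4)
  fa <- fit_model(default_model_catalog()[["autocatalytic"]], obs, n_starts = 4)
  expect_lte(fn$RSS, f1$RSS * (1 + 1e-6))
  expect_lte(fa$RSS, fn$RSS * (1 + 1e-3)) # same grid of starts, one more dof
})

test_that("fits are invariant to row order and bit-reproducible", {
  obs <- make_first_order_obs(sigma = 0.008, seed = 21)
  fit_a <- fit_model(first_order_spec(), obs, n_starts = 4)
  set.seed(77)
  perm <- sample(nrow(obs))
  fit_b <- fit_model(first_order_spec(), obs[perm, ], n_starts = 4)
  expect_equal(fit_b$estimate, fit_a$estimate, tolerance = 1e-6)
  fit_c <- fit_model(first_order_spec(), obs, n_starts = 4)
  expect_identical(fit_c$estimate, fit_a$estimate)
})

test_that("concentration exponent is recovered and reduces correctly", {
  cfg <- akm_presets()[["concentration-dimer"]]
  gen <- generate_dataset(cfg, seed = 31)
  obs <- to_extent(gen$dataset, cfg$transform)
  spec_p <- default_model_catalog(concentration_dependent = TRUE)[["first-order"]]
  fit <- fit_concentration_dependent(spec_p, obs, n_starts = 4)
  expect_lt(abs(fit$params[["p1"]] - 1), 0.15)
  # p fixed at 0 equals the concentration-blind fit
  fit0 <- fit_model(first_order_spec(), obs, n_starts = 4)
  obs_blind <- obs; obs_blind$C <- 1
  fit_blind <- fit_model(first_order_spec(), obs_blind, n_starts = 4)
  expect_equal(fit0$estimate, fit_blind$estimate, tolerance = 1e-6)
  # identical curves at two concentrations force p towards 0
  obs_same <- rbind(make_first_order_obs(), make_first_order_obs())
  obs_same$C <- rep(c(50, 150), each = nrow(obs_same) / 2)
  fit_same <- fit_concentration_dependent(spec_p, obs_same, n_starts = 4)
  expect_lt(abs(fit_same$params[["p1"]]), 0.05)
  # identifiability guards
  one_conc <- obs[obs$C == 50, ]
  expect_error(fit_concentration_dependent(spec_p, one_conc), "identifiable")
  expect_error(fit_concentration_dependent(first_order_spec(), obs),
               "no free concentration exponent")
})

test_that("robustness check flags a pathway change above the fitted range", {
  # single pathway: identical parameters on nested temperature ranges
  obs <- make_first_order_obs()
  rc <- robustness_check(first_order_spec(), obs,
                         ranges = list(c(5, 40), c(5, 25)), n_starts = 4)
  expect_equal(rc$verdict, "robust")
  expect_lt(max(abs(rc$deltas$rel_delta)), 1e-4)
  # two-regime data: low-T arms follow Ea = 80 kJ/mol, arms above 45 degC
  # follow a different pathway with Ea = 160 kJ/mol
  k_lo <- function(Tk) arrhenius_k(24.5, 8e4, Tk)
  k_hi <- function(Tk) arrhenius_k(24.5 + 8e4 / (R_GAS * 322.15), 1.6e5, Tk)
  times <- c(0, 7.6, 15.2, 30.4, 60.9, 91.3, 182.6)
  obs2 <- do.call(rbind, lapply(c(5, 25, 40, 50, 55), function(Ta) {
    Tk <- Ta + 273.15
    k <- if (Ta <= 45) k_lo(Tk) else k_hi(Tk)
    data.frame(time = times, temp_K = Tk, alpha = 1 - exp(-k * times), C = 1)
  }))
  rc2 <- robustness_check(first_order_spec(), obs2,
                          ranges = list(c(5, 55), c(5, 40)), n_starts = 4)
  expect_equal(rc2$verdict, "not robust")
  expect_gt(max(abs(rc2$deltas$rel_delta[rc2$deltas$parameter == "Ea1"])), 0.2)
  # a single full-range interval: deltas vanish
  rc3 <- robustness_check(first_order_spec(), obs,
                          ranges = list(c(5, 40)), n_starts = 4)
  expect_lt(max(abs(rc3$deltas$rel_delta)), 1e-8)
  # ranges leaving < 2 arms are skipped with a warning
  expect_warning(robustness_check(first_order_spec(), obs,
                                  ranges = list(c(0, 10)), n_starts = 2),
                 "skipped")
})
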