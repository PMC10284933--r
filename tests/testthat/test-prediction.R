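# a hand-built degenerate band for crossing-logic tests (linear growth of
# 1 %/month, optional symmetric width in attribute units)
linear_band <- function(rate_per_month = 1, width = 0, y0 = 0,
                        horizon_months = 12, direction = 1) {
  tt <- seq(0, horizon_months * DAYS_PER_MONTH, length.out = 400)
  central <- y0 + direction * rate_per_month * tt / DAYS_PER_MONTH
  structure(data.frame(time = tt, central = central,
                       lower = central - width, upper = central + width),
            class = c("prediction_band", "data.frame"),
            level = 0.95,
            transform = attribute_transform(y0 = y0, span = 100,
                                            direction = direction))
}

test_that("shelf-life crossings are exact on linear trajectories", {
  # 1 %/month zero-order growth, limit +5 % over baseline, no uncertainty
  est <- shelf_life(linear_band(), spec_limit = 5)
  expect_equal(est$t_central / DAYS_PER_MONTH, 5, tolerance = 1e-6)
  expect_equal(est$t_band, est$t_central)
  expect_false(est$zero_shelf_life)
  # widening the band while holding the central curve shortens t_band
  widths <- c(0, 0.5, 1, 2)
  tb <- vapply(widths, function(w)
    shelf_life(linear_band(width = w), spec_limit = 5)$t_band, 0)
  expect_true(all(diff(tb) < 0))
  expect_equal(shelf_life(linear_band(width = 1), 5)$t_central,
               shelf_life(linear_band(width = 0), 5)$t_central)
  # limit above the asymptote of a saturating model: beyond horizon
  sat <- linear_band()
  sat$central <- 4 * (1 - exp(-sat$time / 100))
  sat$upper <- sat$central; sat$lower <- sat$central
  est_sat <- shelf_life(sat, spec_limit = 5)
  expect_true(is.infinite(est_sat$t_central))
  # limit already violated at t0
  est0 <- shelf_life(linear_band(y0 = 10), spec_limit = 5)
  expect_true(est0$zero_shelf_life)
  expect_equal(est0$t_central, 0)
})

test_that("raising the limit never shortens the central shelf-life", {
  b <- quick_band(seed = 2, B = 120)
  limits <- c(95, 90, 85, 80)
  tc <- vapply(limits, function(L) shelf_life(b, L, direction = -1)$t_central, 0)
  expect_true(all(diff(tc) > 0)) # lower potency limit -> longer shelf-life
})

test_that("ICH Q1E baseline reproduces the exact linear crossing", {
  # noiseless y = 100 - 0.5 t(months), limit 94 -> 12 months
  tm <- c(0, 2, 4, 6, 9, 12, 18)
  ds <- stability_dataset(tm * DAYS_PER_MONTH, rep(5, 7), 100 - 0.5 * tm,
                         direction = -1)
  est <- ich_q1e_baseline(ds, spec_limit = 94)
  expect_equal(est$t_shelf / DAYS_PER_MONTH, 12, tolerance = 1e-4)
  expect_equal(est$slope * DAYS_PER_MONTH, -0.5, tolerance = 1e-10)
  # constant data: no crossing, flagged degenerate
  ds_const <- stability_dataset(tm * DAYS_PER_MONTH, rep(5, 7), rep(100, 7),
                                direction = -1)
  est_c <- ich_q1e_baseline(ds_const, spec_limit = 94)
  expect_true(is.infinite(est_c$t_shelf))
  expect_true(est_c$degenerate)
  # improving attribute (wrong-sign slope): beyond horizon
  ds_up <- stability_dataset(tm * DAYS_PER_MONTH, rep(5, 7), 100 + 0.1 * tm,
                             direction = -1)
  expect_true(is.infinite(ich_q1e_baseline(ds_up, 94)$t_shelf))
  expect_error(ich_q1e_baseline(ds[1:2, ], 94), ">= 3 time points")
})

test_that("a 1-day excursion at 10x storage rate costs 9 extra storage-days", {
  # choose Ea so that k(T_exc) = 10 k(5 degC) exactly
  Ea <- 1e5
  T_exc <- 1 / (1 / 278.15 - R_GAS * log(10) / Ea) - 273.15
  p <- kinetic_params(lnA1 = 20, Ea1 = Ea, n1 = 0)
  prof <- generate_excursion_profile(5, list(list(start = 10, duration = 1,
                                                  temp_C = T_exc)),
                                     horizon_days = 30, interpolation = "step")
  eq <- equivalent_days(p, prof, ref_temp_C = 5)
  expect_equal(eq, 30 + 9, tolerance = 1e-9)
  # zero-order: degradation is proportional to the rate integral, so the
  # excursion adds exactly 9 storage-days of damage
  k5 <- arrhenius_k(20, Ea, 278.15)
  cur <- integrate_extent(p, prof, c(0, 30), alpha0 = 0)
  expect_equal(cur$alpha[2] / k5, 39, tolerance = 1e-6)
})

test_that("excursion placement does not matter for separable one-step kinetics", {
  p <- kinetic_params(lnA1 = 26, Ea1 = 8e4, n1 = 1)
  early <- generate_excursion_profile(5, list(list(start = 1, duration = 3,
                                                   temp_C = 25)), 1000)
  late <- generate_excursion_profile(5, list(list(start = 990, duration = 3,
                                                  temp_C = 25)), 1000)
  a_early <- integrate_extent(p, early, c(0, 1000))$alpha[2]
  a_late <- integrate_extent(p, late, c(0, 1000))$alpha[2]
  expect_equal(a_early, a_late, tolerance = 1e-7)
})

test_that("excursion monitoring under a constant profile is the storage band", {
  b <- quick_band(seed = 10, B = 120)
  em <- excursion_monitor(b, constant_profile(5), grid = b$time)
  expect_identical(em$trajectory$central, b$central)
  expect_identical(em$trajectory$lower, b$lower)
  expect_identical(em$trajectory$upper, b$upper)
  expect_equal(em$excess_days, 0, tolerance = 1e-8)
  expect_match(em$profile_checksum, "^[0-9a-f]{32}$")
  # gap annotation on sparse logger records
  sparse <- temperature_profile(c(0, 100, 101), temp_C = c(5, 5, 5))
  expect_warning(excursion_monitor(b, sparse, gap_warn_days = 30), "gaps")
})

test_that("batch comparison separates identical and accelerated batches", {
  cfg <- akm_presets()[["live-attenuated-titer"]]
  gen <- generate_dataset(cfg, seed = 14)
  obs <- to_extent(gen$dataset, cfg$transform)
  ranking <- screen_models(list(first_order_spec()), obs, n_starts = 2)
  band <- residual_bootstrap(ranking, profile = constant_profile(5),
                             transform = cfg$transform, B = 200,
                             level = 0.99, seed = 14)
  # batch compared against itself: comparable with zero parameter deltas
  self <- compare_batches(band, gen$dataset, cfg$transform)
  expect_equal(self$verdict, "comparable")
  expect_equal(unname(self$deltas), c(0, 0), tolerance = 1e-6)
  expect_gte(self$inclusion, 0.95)
  # a batch degrading twice as fast: clearly not comparable
  cfg2 <- cfg
  cfg2$params <- kinetic_params(lnA1 = cfg$params[["lnA1"]] + log(2),
                                Ea1 = cfg$params[["Ea1"]], n1 = 1)
  gen2 <- generate_dataset(cfg2, seed = 15)
  fast <- compare_batches(band, gen2$dataset, cfg$transform)
  expect_equal(fast$verdict, "not comparable")
  expect_lt(fast$inclusion, 0.8)
  expect_gt(abs(fast$deltas[["k_ref"]]), 0.5)
  # disjoint temperature arms refuse the comparison
  ds_far <- stability_dataset(c(0, 10, 20, 30), rep(60, 4), c(6.5, 6, 5.5, 5),
                              direction = -1)
  expect_error(compare_batches(band, ds_far, cfg$transform), "refused")
})
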