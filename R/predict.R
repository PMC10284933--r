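# Downstream applications of a fitted kinetic model: shelf-life estimation,
# the classical ICH Q1E regression baseline, cold-chain excursion monitoring
# and batch-to-batch comparison.

# first time at which a curve crosses a limit; bracketing + bisection on the
# linear interpolant, resolved to 0.01 day. Inf = no crossing on the grid.
first_crossing <- function(times, values, limit, direction) {
  crossed <- if (direction > 0) values >= limit else values <= limit
  if (crossed[1]) return(0)
  i <- which(crossed)[1]
  if (is.na(i)) return(Inf)
  f <- stats::approxfun(times, values - limit)
  stats::uniroot(f, lower = times[i - 1], upper = times[i],
                 tol = 0.005)$root
}

#' Shelf-life from a predictive band
#'
#' The shelf-life is the first time the predicted attribute (central curve)
#' crosses the specification limit under the storage profile; the
#' conservative estimate uses the band edge nearer the limit (upper edge for
#' attributes that grow with degradation, lower edge for those that fall).
#'
#' @param band a [residual_bootstrap()] band (>= 100 grid points advised).
#' @param spec_limit specification limit in attribute units.
#' @param direction +1/-1; defaults to the band transform's direction.
#' @return Object of class \code{"shelf_life_estimate"} with crossing times
#'   \code{t_central} and \code{t_band} in days (Inf = beyond the simulated
#'   horizon) and a \code{zero_shelf_life} flag when the limit is already
#'   violated at the start.
#' @export
shelf_life <- function(band, spec_limit, direction = NULL) {
  stopifnot(inherits(band, "prediction_band"))
  if (is.null(direction)) direction <- attr(band, "transform")$direction
  t_central <- first_crossing(band$time, band$central, spec_limit, direction)
  edge <- if (direction > 0) band$upper else band$lower
  t_band <- first_crossing(band$time, edge, spec_limit, direction)
  structure(list(t_central = t_central, t_band = t_band,
                 spec_limit = spec_limit, direction = direction,
                 level = attr(band, "level"), horizon = max(band$time),
                 zero_shelf_life = t_central == 0),
            class = "shelf_life_estimate")
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  fmt <- function(t) if (is.infinite(t)) "beyond horizon"
    else sprintf("%.1f d (%.1f months)", t, t / DAYS_PER_MONTH)
  cat("Shelf-life at limit", x$spec_limit, "\n")
  cat("  central curve :", fmt(x$t_central), "\n")
  cat(sprintf("  %.0f%% band edge: %s\n", 100 * x$level, fmt(x$t_band)))
  if (x$zero_shelf_life) cat("  WARNING: limit already violated at t = 0\n")
  invisible(x)
}

#' Classical ICH Q1E regression baseline
#'
#' Ordinary least-squares line through the storage-temperature arm only,
#' with shelf-life taken at the earliest time where the one-sided 95%
#' confidence limit on the regression mean crosses the specification limit
#' (single-batch ICH Q1E convention). Serves as the comparison point for the
#' kinetic-model estimate.
#'
#' @param ds a [stability_dataset].
#' @param spec_limit specification limit in attribute units.
#' @param storage_temp_C arm to regress on; default the coldest arm.
#' @param level one-sided confidence level (default 0.95).
#' @param horizon_days search horizon for the crossing.
#' @return Object of class \code{"ich_estimate"}: shelf-life \code{t_shelf}
#'   (days; Inf when no crossing), the fitted \code{lm}, its slope and the
#'   arm used.
#' @export
ich_q1e_baseline <- function(ds, spec_limit, storage_temp_C = NULL,
                             level = 0.95, horizon_days = 10 * 365.25) {
  stopifnot(inherits(ds, "stability_dataset"))
  direction <- attr(ds, "attribute")$direction
  if (is.null(storage_temp_C)) storage_temp_C <- min(arms(ds))
  sub <- ds[round(ds$temp_C, 1) == round(storage_temp_C, 1), , drop = FALSE]
  if (length(unique(sub$time_days)) < 3)
    stop("ICH baseline needs >= 3 time points at the storage temperature",
         call. = FALSE)
  fit <- stats::lm(value ~ time_days, data = sub)
  slope <- stats::coef(fit)[["time_days"]]
  grid <- seq(0, horizon_days, length.out = 2000)
  pr <- stats::predict(fit, newdata = data.frame(time_days = grid),
                       se.fit = TRUE)
  tq <- stats::qt(level, df = fit$df.residual)
  cl <- pr$fit + direction * tq * pr$se.fit # one-sided CL on the mean,
                                            # on the degrading side
  degenerate <- direction * slope <= 0
  t_shelf <- if (degenerate) Inf else first_crossing(grid, cl, spec_limit, direction)
  if (!degenerate && is.infinite(t_shelf)) {
    # line degrades but has not crossed in the horizon: solve algebraically
    b <- stats::coef(fit)
    t_lin <- (spec_limit - b[[1]]) / b[[2]]
    if (is.finite(t_lin) && t_lin > horizon_days) t_shelf <- Inf
  }
  structure(list(t_shelf = t_shelf, fit = fit, slope = slope,
                 intercept = stats::coef(fit)[[1]],
                 storage_temp_C = storage_temp_C, level = level,
                 spec_limit = spec_limit, degenerate = degenerate),
            class = "ich_estimate")
}

#' @export
print.ich_estimate <- function(x, ...) {
  cat(sprintf("ICH Q1E baseline at %.1f degC: y = %.4g %+.4g t\n",
              x$storage_temp_C, x$intercept, x$slope))
  cat("  shelf-life:",
      if (is.infinite(x$t_shelf)) "beyond horizon"
      else sprintf("%.1f d (%.1f months)", x$t_shelf, x$t_shelf / DAYS_PER_MONTH),
      "\n")
  invisible(x)
}

# integral of the step-1 Arrhenius rate constant over a profile
profile_rate_integral <- function(params, profile, t0, t1, C = 1) {
  p <- as_kinetic_params(params)
  lnk_pref <- p[["lnA1"]] + p[["p1"]] * log(C)
  kfun <- function(t) exp(lnk_pref - p[["Ea1"]] / (R_GAS * temperature_at(profile, t)))
  brk <- sort(unique(c(t0, profile$time[profile$time > t0 & profile$time < t1], t1)))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    Ta <- temperature_at(profile, a)
    Tb <- temperature_at(profile, b - 1e-9)
    if (profile$interpolation == "step" || abs(Ta - Tb) < 1e-12) {
      Tm <- temperature_at(profile, (a + b) / 2)
      total <- total + exp(lnk_pref - p[["Ea1"]] / (R_GAS * Tm)) * (b - a)
    } else {
      total <- total + stats::integrate(kfun, a, b, rel.tol = 1e-10)$value
    }
  }
  total
}

#' Time at a reference temperature equivalent to a profile
#'
#' \eqn{\tau = \int k_1(T(s)) ds / k_1(T_{ref})} using the step-1 rate
#' constant: the number of isothermal reference-temperature days that cause
#' the same step-1 rate exposure as the profile. Exact for one-step models
#' whose rate separates as \eqn{k(T) f(\alpha)}; advisory for two-step fits.
#'
#' @param params a [kinetic_params] vector.
#' @param profile a [temperature_profile].
#' @param t_end end of the exposure window (days); default profile end.
#' @param ref_temp_C reference temperature (default 5 degC).
#' @param t0 start of the window.
#' @param C concentration covariate.
#' @return Equivalent days at the reference temperature.
#' @export
equivalent_days <- function(params, profile, t_end = max(profile$time),
                            ref_temp_C = 5, t0 = profile$time[1], C = 1) {
  p <- as_kinetic_params(params)
  k_ref <- arrhenius_k(p[["lnA1"]] + p[["p1"]] * log(C), p[["Ea1"]],
                       ref_temp_C + 273.15)
  profile_rate_integral(p, profile, t0, t_end, C = C) / k_ref
}

#' Monitor degradation over a recorded temperature history
#'
#' Integrates the fitted ensemble over an arbitrary temperature trace (e.g.
#' an electronic-logger record including cold-chain excursions), returning
#' the central attribute trajectory with its pointwise band, plus the
#' degradation budget consumed expressed as equivalent days at the
#' recommended storage temperature. With a constant profile and the same
#' grid this reproduces the storage prediction band exactly.
#'
#' @param band a [residual_bootstrap()] band (supplies ensemble, transform
#'   and central model).
#' @param profile the recorded [temperature_profile].
#' @param grid output times (days); default: profile knots plus 200 evenly
#'   spaced points over the profile span.
#' @param ref_temp_C reference storage temperature for the budget (5 degC).
#' @param gap_warn_days annotate gaps between profile knots longer than this
#'   (default Inf = off).
#' @return Object of class \code{"excursion_report"}: trajectory data.frame
#'   (\code{time}, \code{temperature_C}, \code{central}, \code{lower},
#'   \code{upper}), \code{equivalent_days}, \code{elapsed_days},
#'   \code{excess_days} and the input profile checksum.
#' @export
excursion_monitor <- function(band, profile, grid = NULL, ref_temp_C = 5,
                              gap_warn_days = Inf) {
  stopifnot(inherits(band, "prediction_band"),
            inherits(profile, "temperature_profile"))
  top <- attr(band, "top_fit")
  transform <- attr(band, "transform")
  if (is.null(grid)) {
    t1 <- max(profile$time)
    t0 <- profile$time[1]
    if (t1 <= t0) t1 <- t0 + 1
    grid <- sort(unique(c(profile$time, seq(t0, t1, length.out = 200))))
  }
  gaps <- character()
  if (is.finite(gap_warn_days) && length(profile$time) > 1) {
    dg <- diff(profile$time)
    bad <- which(dg > gap_warn_days)
    if (length(bad)) {
      gaps <- sprintf("gap of %.2f d after t = %.2f d", dg[bad],
                      profile$time[bad])
      warning("temperature record has gaps longer than ", gap_warn_days,
              " days", call. = FALSE)
    }
  }
  ep <- predict_ensemble(attr(band, "ensemble"), profile, grid, transform,
                         attr(band, "level"), central_params = top$params,
                         C = unique(top$data$C)[1], alpha0 = top$alpha0)
  elapsed <- max(grid) - grid[1]
  eq <- equivalent_days(top$params, profile, t_end = max(grid),
                        ref_temp_C = ref_temp_C, t0 = grid[1],
                        C = unique(top$data$C)[1])
  tmp <- tempfile(fileext = ".csv")
  write_profile_csv(profile, tmp)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(list(trajectory = data.frame(time = grid,
                                         temperature_C = temperature_at(profile, grid) - 273.15,
                                         central = ep$central,
                                         lower = pmin(ep$lower, ep$central),
                                         upper = pmax(ep$upper, ep$central)),
                 equivalent_days = eq, elapsed_days = elapsed,
                 excess_days = eq - elapsed, ref_temp_C = ref_temp_C,
                 level = attr(band, "level"), gaps = gaps,
                 profile_checksum = checksum),
            class = "excursion_report")
}

#' @export
print.excursion_report <- function(x, ...) {
  cat(sprintf("Excursion monitor: %.2f elapsed days = %.2f equivalent days at %g degC (excess %.2f d)\n",
              x$elapsed_days, x$equivalent_days, x$ref_temp_C, x$excess_days))
  if (length(x$gaps)) cat("  record gaps:", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

#' Batch-to-batch stability comparison
#'
#' Judges whether a new batch behaves like a reference batch by (i) the
#' fraction of the new batch's observations falling inside the reference
#' batch's bootstrap band at matching time/temperature, and (ii) the
#' relative differences in activation energy and in the rate constant at a
#' reference temperature between independent fits of the two batches.
#'
#' @param band_A reference-batch [residual_bootstrap()] band (99% level per
#'   common practice).
#' @param ds_B the new batch as a [stability_dataset].
#' @param transform shared [attribute_transform] (same attribute on both
#'   batches).
#' @param threshold minimum band-inclusion fraction for the verdict
#'   "comparable" (default 0.95).
#' @param ref_temp_C temperature at which rate constants are compared (25).
#' @param seed RNG seed for the residual noise added to the ensemble
#'   predictions (prediction-interval semantics: individual measurements of
#'   a truly comparable batch should fall inside the band at about the band
#'   level).
#' @param ... passed to [fit_model()] for the batch-B refit.
#' @return Object of class \code{"batch_comparison"}: inclusion fraction,
#'   parameter deltas, both fits and the verdict.
#' @export
compare_batches <- function(band_A, ds_B, transform, threshold = 0.95,
                            ref_temp_C = 25, seed = 1, ...) {
  stopifnot(inherits(band_A, "prediction_band"),
            inherits(ds_B, "stability_dataset"))
  fit_A <- attr(band_A, "top_fit")
  obs_B <- to_extent(ds_B, transform)
  arms_A <- sort(unique(round(fit_A$data$temp_K - 273.15, 1)))
  if (length(intersect(arms_A, arms(ds_B))) == 0)
    stop("no overlapping temperature arms between batches; comparison refused",
         call. = FALSE)
  ensemble <- attr(band_A, "ensemble")
  level <- attr(band_A, "level")
  pred <- vapply(ensemble, function(m)
    alpha_model_at(m$params, obs_B, alpha0 = fit_A$alpha0),
    numeric(nrow(obs_B)))
  pred <- matrix(pred, nrow = nrow(obs_B))
  # prediction-interval semantics: add Gaussian measurement noise at the
  # batch-A residual scale to each draw (a Gaussian margin keeps honest
  # tails at the 99% level, where resampling N ~ 20 residuals truncates)
  sd_c <- sqrt(fit_A$RSS / fit_A$N)
  if (!is.null(seed)) set.seed(seed)
  pred <- pred + matrix(stats::rnorm(length(pred), 0, sd_c), nrow = nrow(pred))
  qs <- quantile_band(t(pred), level)
  val_lo <- predict_attribute(pmin(qs[1, ], qs[2, ]), transform)
  val_hi <- predict_attribute(pmax(qs[1, ], qs[2, ]), transform)
  lo <- pmin(val_lo, val_hi); hi <- pmax(val_lo, val_hi)
  inside <- ds_B$value >= lo - 1e-12 & ds_B$value <= hi + 1e-12
  inclusion <- mean(inside)
  fit_B <- fit_model(fit_A$spec, obs_B, ...)
  kA <- arrhenius_k(fit_A$params[["lnA1"]], fit_A$params[["Ea1"]],
                    ref_temp_C + 273.15)
  kB <- arrhenius_k(fit_B$params[["lnA1"]], fit_B$params[["Ea1"]],
                    ref_temp_C + 273.15)
  deltas <- c(Ea1 = (fit_B$params[["Ea1"]] - fit_A$params[["Ea1"]]) /
                fit_A$params[["Ea1"]],
              k_ref = kB / kA - 1)
  verdict <- if (inclusion >= threshold) "comparable" else "not comparable"
  structure(list(inclusion = inclusion, level = level, threshold = threshold,
                 deltas = deltas, ref_temp_C = ref_temp_C,
                 fit_A = fit_A, fit_B = fit_B, inside = inside,
                 verdict = verdict),
            class = "batch_comparison")
}

#' @export
print.batch_comparison <- function(x, ...) {
  cat(sprintf("Batch comparison: %.1f%% of new-batch points inside the %.0f%% band (threshold %.0f%%) -> %s\n",
              100 * x$inclusion, 100 * x$level, 100 * x$threshold,
              toupper(x$verdict)))
  cat(sprintf("  delta Ea = %+.2f%%, delta k(%g degC) = %+.2f%%\n",
              100 * x$deltas[["Ea1"]], x$ref_temp_C, 100 * x$deltas[["k_ref"]]))
  invisible(x)
}
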