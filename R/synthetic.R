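# Synthetic accelerated-stability scenarios. Each preset fixes a true
# kinetic law, a study design (temperature arms and pull points) and an
# attribute transform so that every stage of the workflow can be exercised
# and calibrated without proprietary product data.

default_times_months <- c(0, 0.25, 0.5, 1, 2, 3, 6)

#' Define a synthetic stability scenario
#'
#' A scenario bundles the true kinetic parameters and model structure, the
#' study design (arms and pull points), the attribute transform and the
#' noise model. Use [akm_presets()] for ready-made scenarios.
#'
#' @param name scenario label.
#' @param params true [kinetic_params].
#' @param structure_name name of the catalog model that generated the data
#'   (the "true structure" for selection checks).
#' @param arms_C incubation temperatures (degC), default 5/25/40.
#' @param times_months pull points per arm (months).
#' @param transform [attribute_transform] from extent to measured units.
#' @param sigma additive Gaussian noise s.d. in attribute units (default:
#'   0.005 of the span, i.e. sigma_alpha = 0.005).
#' @param noise \code{"additive"} or \code{"proportional"} (coefficient of
#'   variation \code{sigma} applied to the attribute value).
#' @param concentrations optional protein concentrations; the design is
#'   replicated at each and the covariate recorded.
#' @param seed default RNG seed for [generate_dataset()].
#' @return Object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(name, params, structure_name,
                            arms_C = c(5, 25, 40),
                            times_months = default_times_months,
                            transform, sigma = 0.005 * transform$span,
                            noise = c("additive", "proportional"),
                            concentrations = NULL, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(transform, "attribute_transform"))
  structure(list(name = name, params = as_kinetic_params(params),
                 structure_name = structure_name, arms_C = arms_C,
                 times_months = times_months, transform = transform,
                 sigma = sigma, noise = noise,
                 concentrations = concentrations, seed = seed),
            class = "scenario_config")
}

#' Built-in stability scenarios
#'
#' Five presets spanning the degradation behaviours the method is used on:
#' \describe{
#'   \item{mab-acidic-variants}{one-step second-order growth of acidic
#'     species of a mAb (Ea = 100 kJ/mol).}
#'   \item{hmw-aggregation}{slow zero-order HMW formation
#'     (Ea = 110 kJ/mol), calibrated to 0.0046 HMW-\% per day at 25 degC.}
#'   \item{decelerating-vaccine}{two-step competitive potency loss: a fast
#'     low-barrier step (v = 0.3, Ea = 30 kJ/mol) followed by a slow
#'     high-barrier step (Ea = 100 kJ/mol), giving the fast-drop-then-
#'     plateau shape typical of vaccines.}
#'   \item{concentration-dimer}{first-order dimerization whose rate scales
#'     linearly with protein concentration (p = 1), at 50 and 150 mg/mL.}
#'   \item{live-attenuated-titer}{first-order loss of infectious titer in
#'     log10 units (Ea = 80 kJ/mol).}
#' }
#'
#' @return Named list of [scenario_config] objects.
#' @export
akm_presets <- function() {
  presets <- list(
    scenario_config(
      "mab-acidic-variants",
      kinetic_params(lnA1 = log(6.7e-3) + 1e5 / (R_GAS * 313.15), Ea1 = 1e5,
                     n1 = 2, m1 = 0),
      structure_name = "nth-order",
      transform = attribute_transform(y0 = 18, span = 60, direction = 1,
                                      name = "acidic variants", unit = "%")),
    scenario_config(
      "hmw-aggregation",
      kinetic_params(lnA1 = log(4.6e-4) + 1.1e5 / (R_GAS * 298.15), Ea1 = 1.1e5,
                     n1 = 0, m1 = 0),
      structure_name = "zero-order",
      transform = attribute_transform(y0 = 0.5, span = 10, direction = 1,
                                      name = "HMW", unit = "%")),
    scenario_config(
      "decelerating-vaccine",
      kinetic_params(lnA1 = log(0.05) + 3e4 / (R_GAS * 278.15), Ea1 = 3e4,
                     n1 = 1, m1 = 0,
                     lnA2 = log(1.5e-3) + 1e5 / (R_GAS * 313.15), Ea2 = 1e5,
                     n2 = 1, m2 = 0, v = 0.3),
      structure_name = "two-step",
      transform = attribute_transform(y0 = 100, span = 100, direction = -1,
                                      name = "potency", unit = "%")),
    scenario_config(
      "concentration-dimer",
      kinetic_params(lnA1 = log(2e-3) - log(100) + 9e4 / (R_GAS * 313.15),
                     Ea1 = 9e4, n1 = 1, m1 = 0, p1 = 1),
      structure_name = "first-order",
      concentrations = c(50, 150),
      transform = attribute_transform(y0 = 0.2, span = 8, direction = 1,
                                      name = "dimer", unit = "%")),
    scenario_config(
      "live-attenuated-titer",
      kinetic_params(lnA1 = log(0.01) + 8e4 / (R_GAS * 313.15), Ea1 = 8e4,
                     n1 = 1, m1 = 0),
      structure_name = "first-order",
      transform = attribute_transform(y0 = 6.5, span = 6.5, direction = -1,
                                      name = "infectious titer",
                                      unit = "log10 CCID50"))
  )
  names(presets) <- vapply(presets, `[[`, "", "name")
  presets
}

#' Generate a synthetic accelerated-stability dataset
#'
#' Integrates the scenario's true kinetics over every arm, maps extent to
#' attribute units and adds measurement noise. Deterministic for a given
#' seed. The ground truth (parameters, noiseless curves) is returned for
#' recovery tests, along with the stage-1 design report of the realized
#' dataset.
#'
#' @param cfg a [scenario_config] (or a preset name).
#' @param seed RNG seed (overrides the config's seed).
#' @return List with elements \code{dataset} (a [stability_dataset]),
#'   \code{truth} (params, structure name, transform, noiseless curves) and
#'   \code{design} (a [validate_design()] report).
#' @export
generate_dataset <- function(cfg, seed = NULL) {
  if (is.character(cfg)) {
    presets <- akm_presets()
    if (!cfg %in% names(presets))
      stop("unknown preset '", cfg, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    cfg <- presets[[cfg]]
  }
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  tr <- cfg$transform
  times <- sort(unique(cfg$times_months)) * DAYS_PER_MONTH
  concs <- if (is.null(cfg$concentrations)) NA else cfg$concentrations
  rows <- list(); curves <- list()
  for (C in concs) {
    Cuse <- if (is.na(C)) 1 else C
    for (Ta in cfg$arms_C) {
      cur <- integrate_extent(cfg$params, constant_profile(Ta),
                              times = if (times[1] > 0) c(0, times) else times,
                              C = Cuse)
      a <- cur$alpha[match(times, cur$time)]
      y <- tr$y0 + tr$direction * tr$span * a
      noise <- if (cfg$sigma <= 0) 0
               else if (cfg$noise == "additive") stats::rnorm(length(y), 0, cfg$sigma)
               else y * stats::rnorm(length(y), 0, cfg$sigma)
      rows[[length(rows) + 1]] <- data.frame(
        time_days = times, temp_C = Ta, value = y + noise,
        concentration = C, batch = NA)
      curves[[length(curves) + 1]] <- data.frame(
        time_days = times, temp_C = Ta, concentration = C,
        alpha = a, value = y)
    }
  }
  df <- do.call(rbind, rows)
  ds <- stability_dataset(df$time_days, df$temp_C, df$value,
                          concentration = df$concentration,
                          attribute = tr$name, unit = tr$unit,
                          direction = tr$direction)
  truth_curves <- do.call(rbind, curves)
  # flag designs whose truth saturates well before the hot arm is sampled out
  hot <- truth_curves[truth_curves$temp_C == max(cfg$arms_C), ]
  if (any(hot$alpha[hot$time_days <= stats::median(times)] >= 0.999))
    warning("saturated design: the true extent reaches ~1 early at the hottest arm",
            call. = FALSE)
  list(dataset = ds,
       truth = list(params = cfg$params, structure_name = cfg$structure_name,
                    transform = tr, curves = truth_curves, sigma = cfg$sigma,
                    seed = seed),
       design = validate_design(ds, tr))
}

#' Build a storage profile with temperature excursions
#'
#' Piecewise-linear profile holding a storage temperature, with excursions
#' to other temperatures connected by short linear ramps (default 1 h).
#' Excursions must be non-overlapping and inside the horizon.
#'
#' @param storage_temp_C recommended storage temperature (degC).
#' @param excursions list of \code{list(start, duration, temp_C)} (days,
#'   days, degC): the excursion ramps up at \code{start}, holds until
#'   \code{start + duration}, then ramps back.
#' @param horizon_days profile end (days).
#' @param ramp_hours ramp time between levels (default 1 h).
#' @param interpolation \code{"linear"} or \code{"step"} (instant switches;
#'   ramps ignored).
#' @return A [temperature_profile].
#' @export
generate_excursion_profile <- function(storage_temp_C, excursions = list(),
                                       horizon_days, ramp_hours = 1,
                                       interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  ramp <- ramp_hours / 24
  if (length(excursions)) {
    starts <- vapply(excursions, `[[`, 0, "start")
    exc <- excursions[order(starts)]
    ends <- vapply(exc, function(e) e$start + e$duration + ramp, 0)
    starts <- sort(starts)
    if (any(starts <= 0) || any(ends > horizon_days))
      stop("excursions must lie strictly inside (0, horizon)", call. = FALSE)
    if (length(exc) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("overlapping excursions", call. = FALSE)
  } else exc <- list()
  if (interpolation == "step") {
    t <- 0; temps <- storage_temp_C
    for (e in exc) {
      t <- c(t, e$start, e$start + e$duration)
      temps <- c(temps, e$temp_C, storage_temp_C)
    }
    if (max(t) < horizon_days) { t <- c(t, horizon_days); temps <- c(temps, storage_temp_C) }
    return(temperature_profile(t, temp_C = temps, interpolation = "step"))
  }
  t <- 0; temps <- storage_temp_C
  for (e in exc) {
    t <- c(t, e$start, e$start + ramp, e$start + e$duration,
           e$start + e$duration + ramp)
    temps <- c(temps, storage_temp_C, e$temp_C, e$temp_C, storage_temp_C)
  }
  if (max(t) < horizon_days) { t <- c(t, horizon_days); temps <- c(temps, storage_temp_C) }
  temperature_profile(t, temp_C = temps, interpolation = "linear")
}
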