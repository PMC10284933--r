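# Catalog screening, information-criterion weights and the multiple-model
# bootstrap (MMB) that turns fit uncertainty into predictive bands.

ic_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Screen a catalog of kinetic models against one dataset
#'
#' Fits every model of the catalog, computes Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} on the
#' small-sample-corrected AICc (and the analogous BIC weights), and ranks
#' models by the combined weight \code{(wAIC + wBIC)/2}. Ties are broken in
#' favour of fewer free parameters. Models whose optimization fails are
#' excluded with their error recorded.
#'
#' @param catalog list of [model_spec]s, e.g. [default_model_catalog()].
#' @param data extent observations (see [fit_model()]).
#' @param design optional [validate_design()] report; a failed design aborts
#'   the screening unless \code{force = TRUE} (then a warning is logged).
#' @param force proceed despite a failed design report.
#' @param ... passed to [fit_model()] (e.g. \code{n_starts}).
#' @return Object of class \code{"model_ranking"}: a ranking table, the fits,
#'   and any per-model failure diagnostics.
#' @export
screen_models <- function(catalog, data, design = NULL, force = FALSE, ...) {
  if (!is.null(design) && design$status == "fail") {
    if (!force)
      stop("study design fails stage-1 rules; rerun with force = TRUE to override",
         call. = FALSE)
    warning("screening forced despite a failed study-design validation",
            call. = FALSE)
  }
  fits <- list(); failures <- list()
  for (spec in catalog) {
    f <- tryCatch(fit_model(spec, data, ...), error = function(e) e)
    if (inherits(f, "error")) {
      failures[[spec$name]] <- conditionMessage(f)
    } else if (!f$converged) {
      failures[[spec$name]] <- sprintf("optimizer did not converge (info = %d)", f$info)
    } else {
      fits[[spec$name]] <- f
    }
  }
  if (length(fits) == 0)
    stop("every catalog model failed to fit:\n  ",
         paste(names(failures), unlist(failures), sep = ": ", collapse = "\n  "),
         call. = FALSE)
  tab <- data.frame(
    model = names(fits),
    structure = vapply(fits, function(f) f$spec$structure, ""),
    K = vapply(fits, `[[`, 0, "K"),
    N = vapply(fits, `[[`, 0, "N"),
    RSS = vapply(fits, `[[`, 0, "RSS"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    stringsAsFactors = FALSE)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  tab$wAIC <- ic_weights(tab$AICc)
  tab$wBIC <- ic_weights(tab$BIC)
  tab$wCombined <- (tab$wAIC + tab$wBIC) / 2
  ord <- order(-tab$wCombined, tab$K)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[tab$model], failures = failures),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Kinetic model screening (ranked by combined AICc/BIC weight):\n")
  tab <- x$table
  tab$RSS <- signif(tab$RSS, 4)
  for (col in c("AICc", "BIC", "wAIC", "wBIC", "wCombined"))
    tab[[col]] <- round(tab[[col]], 3)
  print(tab[, c("model", "K", "RSS", "AICc", "BIC", "wAIC", "wBIC", "wCombined")])
  if (length(x$failures))
    cat("excluded:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Distribute bootstrap loops across ranked models
#'
#' Allocates a total of B loops proportionally to the combined AIC/BIC
#' weights, using largest-remainder rounding so that the allocation sums
#' exactly to B.
#'
#' @param ranking a [screen_models()] result (or a named weight vector).
#' @param B total number of bootstrap loops (>= 1).
#' @return Named integer vector of per-model loop counts summing to B.
#' @export
allocate_loops <- function(ranking, B) {
  stopifnot(B >= 1)
  w <- if (inherits(ranking, "model_ranking"))
    stats::setNames(ranking$table$wCombined, ranking$table$model) else ranking
  w <- w / sum(w)
  raw <- B * w
  n <- floor(raw)
  rem <- round(B - sum(n))
  if (rem > 0) {
    frac <- raw - n
    give <- order(-frac, -w)[seq_len(rem)]
    n[give] <- n[give] + 1
  }
  stats::setNames(as.integer(n), names(w))
}

quantile_band <- function(mat, level) {
  lo <- (1 - level) / 2
  apply(mat, 2, stats::quantile, probs = c(lo, 1 - lo), names = FALSE,
        type = 7)
}

# deterministic ensemble propagation over a profile; shared by storage bands
# and excursion monitoring so a constant-profile excursion reproduces the
# storage band exactly
predict_ensemble <- function(ensemble, profile, grid, transform, level,
                             central_params, C = 1, alpha0 = 1e-8) {
  central <- predict_attribute(
    integrate_extent(central_params, profile, grid, C = C, alpha0 = alpha0),
    transform)$value
  pred <- vapply(ensemble, function(m)
    predict_attribute(integrate_extent(m$params, profile, grid, C = C,
                                       alpha0 = alpha0), transform)$value,
    numeric(length(grid)))
  pred <- matrix(pred, nrow = length(grid))
  qs <- quantile_band(t(pred), level)
  list(central = central, lower = qs[1, ], upper = qs[2, ], draws = t(pred))
}

#' Residual bootstrap and predictive band at a storage profile
#'
#' Implements the multiple-model bootstrap: loops are allocated across the
#' ranked models with [allocate_loops()]; each loop resamples centered fit
#' residuals with replacement (or draws Gaussian residuals with
#' \code{flavor = "parametric"}), adds them to the fitted extents, refits the
#' loop's model from its original estimate, and the refitted parameter sets
#' form the ensemble. The band at each grid time is the empirical
#' \eqn{((1-level)/2, (1+level)/2)} quantile of the ensemble's predicted
#' attribute values; the central curve is the top-ranked model's original
#' fit.
#'
#' By default the band is a confidence band on the mean trajectory;
#' \code{band_type = "prediction"} additionally adds resampled residual
#' noise to each loop's prediction, widening it into a prediction interval
#' for individual future measurements.
#'
#' @param ranking a [screen_models()] result.
#' @param profile storage [temperature_profile] for the band.
#' @param transform [attribute_transform] mapping extent to attribute units.
#' @param B total bootstrap loops (default 1000; a warning is issued below
#'   100).
#' @param level band level, 0.95 or 0.99.
#' @param seed RNG seed; identical seeds give identical ensembles and bands.
#' @param grid output time grid (days); default is the union of the data
#'   times and 200 evenly spaced points up to \code{horizon_days}.
#' @param horizon_days forecast horizon used for the default grid.
#' @param C concentration covariate for the prediction.
#' @param flavor residual resampling flavor.
#' @param band_type \code{"confidence"} (default) or \code{"prediction"}.
#' @param max_fail abort when more than this fraction of loops fails (0.2).
#' @param maxiter iteration cap for the warm-started refits.
#' @return Object of class \code{"prediction_band"}: a data.frame
#'   (\code{time}, \code{central}, \code{lower}, \code{upper}) with the
#'   ensemble, allocation, level and profile attached as attributes.
#' @export
residual_bootstrap <- function(ranking, profile, transform, B = 1000,
                               level = 0.95, seed = NULL, grid = NULL,
                               horizon_days = 3 * 365.25, C = NULL,
                               flavor = c("nonparametric", "parametric"),
                               band_type = c("confidence", "prediction"),
                               max_fail = 0.2, maxiter = 60) {
  flavor <- match.arg(flavor)
  band_type <- match.arg(band_type)
  stopifnot(inherits(ranking, "model_ranking"))
  if (B < 100) warning("B < 100 loops gives unreliable band quantiles", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  top <- ranking$fits[[1]]
  if (is.null(C)) {
    cs <- unique(top$data$C)
    C <- if (length(cs) == 1) cs else 1
  }
  if (is.null(grid))
    grid <- sort(unique(c(0, top$data$time[top$data$time <= horizon_days],
                          seq(0, horizon_days, length.out = 200))))
  alloc <- allocate_loops(ranking, B)
  ensemble <- list(); n_fail <- 0
  for (name in names(alloc)) {
    nb <- alloc[[name]]
    if (nb == 0) next
    fit <- ranking$fits[[name]]
    res_c <- fit$residuals - mean(fit$residuals)
    sd_c <- sqrt(sum(res_c^2) / fit$N)
    for (b in seq_len(nb)) {
      e <- if (flavor == "nonparametric")
        sample(res_c, fit$N, replace = TRUE) else stats::rnorm(fit$N, 0, sd_c)
      star <- fit$data
      star$alpha <- fit$fitted + e
      refit <- tryCatch(
        fit_model(fit$spec, star, start = fit$estimate, maxiter = maxiter),
        error = function(err) NULL)
      if (is.null(refit)) { n_fail <- n_fail + 1; next }
      ensemble[[length(ensemble) + 1]] <-
        list(model = name, params = refit$params)
    }
  }
  if (n_fail > max_fail * B)
    stop(sprintf("bootstrap aborted: %d of %d loops failed to converge; the band would be unreliable",
                 n_fail, B), call. = FALSE)
  ep <- predict_ensemble(ensemble, profile, grid, transform, level,
                         central_params = top$params, C = C,
                         alpha0 = top$alpha0)
  lower <- ep$lower; upper <- ep$upper
  if (band_type == "prediction") {
    res_attr <- (top$residuals - mean(top$residuals)) * transform$span
    noise <- matrix(sample(res_attr, length(ensemble) * length(grid),
                           replace = TRUE),
                    nrow = length(ensemble))
    qs <- quantile_band(ep$draws + noise, level)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  band <- data.frame(time = grid, central = ep$central,
                     lower = pmin(lower, ep$central),
                     upper = pmax(upper, ep$central))
  structure(band,
            class = c("prediction_band", "data.frame"),
            level = level, profile = profile, transform = transform,
            ensemble = ensemble, allocation = alloc, seed = seed,
            band_type = band_type, top_fit = top, n_fail = n_fail)
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf("Predictive band: level %.0f%%, %d grid points, %d ensemble members (%s)\n",
              100 * attr(x, "level"), nrow(x), length(attr(x, "ensemble")),
              attr(x, "band_type")))
  invisible(x)
}

#' Export a predictive band as CSV
#'
#' Columns: \code{time_days, central, lower, upper, level}.
#' @param band a [residual_bootstrap()] band.
#' @param path output file.
#' @export
write_band_csv <- function(band, path) {
  utils::write.csv(data.frame(time_days = band$time, central = band$central,
                              lower = band$lower, upper = band$upper,
                              level = attr(band, "level")),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a model ranking as JSON
#'
#' @param ranking a [screen_models()] result.
#' @param path optional output file.
#' @return JSON text.
#' @export
ranking_to_json <- function(ranking, path = NULL) {
  txt <- jsonlite::toJSON(list(ranking = ranking$table,
                               failures = ranking$failures),
                          dataframe = "rows", auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
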