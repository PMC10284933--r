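# Nonlinear least-squares estimation of kinetic parameters against
# multi-temperature extent observations.

# model extent at every observation row, grouping rows into isothermal arms
alpha_model_at <- function(pvec, obs, alpha0 = 1e-8, rtol = 1e-8, atol = 1e-10) {
  key <- paste(obs$temp_K, obs$C)
  out <- numeric(nrow(obs))
  v <- pvec[["v"]]
  for (k in unique(key)) {
    idx <- which(key == k)
    T_K <- obs$temp_K[idx[1]]
    C <- obs$C[idx[1]]
    tt <- obs$time[idx]
    ord <- order(tt)
    tu <- tt[ord]
    t_int <- if (tu[1] > 0) c(0, tu) else tu
    step_alpha <- function(lnA, Ea, n, m, pw) {
      lnk <- lnA + if (pw != 0) pw * log(C) else 0
      substep_alpha_cpp(t_int, alpha0, lnk, Ea, n, m, 0, T_K, 0L, rtol, atol)
    }
    a1 <- if (v > 0) step_alpha(pvec[["lnA1"]], pvec[["Ea1"]], pvec[["n1"]],
                                pvec[["m1"]], pvec[["p1"]]) else rep(alpha0, length(t_int))
    a2 <- if (v < 1) step_alpha(pvec[["lnA2"]], pvec[["Ea2"]], pvec[["n2"]],
                                pvec[["m2"]], pvec[["p2"]]) else rep(alpha0, length(t_int))
    a <- v * a1 + (1 - v) * a2
    if (tu[1] > 0) a <- a[-1]
    out[idx[ord]] <- a
  }
  out
}

clamp_start <- function(start, lower, upper) {
  eps <- 1e-9 + 1e-6 * abs(upper - lower)
  pmin(pmax(start, lower + eps), upper - eps)
}

# crude per-arm rate constants and an Arrhenius line through them, used to
# seed the optimizer with a data-driven start
arrhenius_seed <- function(obs) {
  key <- paste(obs$temp_K, obs$C)
  seeds <- do.call(rbind, lapply(unique(key), function(k) {
    idx <- key == k
    tt <- obs$time[idx]; aa <- obs$alpha[idx]
    if (length(unique(tt)) < 2) return(NULL)
    sl <- stats::coef(stats::lm(aa ~ tt))[2]
    data.frame(T_K = obs$temp_K[idx][1], k = max(sl, 1e-8))
  }))
  if (is.null(seeds) || length(unique(seeds$T_K)) < 2)
    return(list(lnA = log(1e-3) + 8e4 / (R_GAS * 313.15), Ea = 8e4))
  fitl <- stats::lm(log(seeds$k) ~ I(1 / seeds$T_K))
  Ea <- max(1.5e4, min(2.8e5, -stats::coef(fitl)[2] * R_GAS))
  lnA <- mean(log(seeds$k) + Ea / (R_GAS * seeds$T_K))
  list(lnA = unname(lnA), Ea = unname(Ea))
}

# data-driven seed for the two-step structure: the fast low-barrier step is
# near-saturated early (its plateau shows as the coldest arm's terminal
# extent), the slow step drives the late-time progress of the hottest arm
two_step_seed <- function(obs) {
  Ts <- sort(unique(obs$temp_K))
  cold <- obs[obs$temp_K == Ts[1], ]
  hot <- obs[obs$temp_K == Ts[length(Ts)], ]
  v0 <- min(max(max(cold$alpha), 0.05), 0.9)
  tq <- unname(stats::quantile(obs$time[obs$time > 0], 0.25))
  Ea1 <- 3e4
  lnA1 <- log(3 / tq) + Ea1 / (R_GAS * mean(Ts))
  a_end <- max(hot$alpha); t_end <- max(hot$time)
  k2 <- max((a_end - v0) / (1 - v0), 0.01) / t_end
  Ea2 <- 1e5
  lnA2 <- log(k2) + Ea2 / (R_GAS * Ts[length(Ts)])
  c(lnA1 = lnA1, Ea1 = Ea1, n1 = 1, m1 = 0.02,
    lnA2 = lnA2, Ea2 = Ea2, n2 = 1, m2 = 0.02, v = v0, p1 = 0, p2 = 0)
}

# deterministic multi-start list for a model spec
make_starts <- function(spec, obs, n_starts) {
  seed <- arrhenius_seed(obs)
  base <- c(n1 = 1, m1 = 0.05, n2 = 1, m2 = 0.05, v = 0.5, p1 = 0, p2 = 0)
  mids <- c(n1 = 1.5, m1 = 1, n2 = 1.5, m2 = 1, v = 0.5, p1 = 0.5, p2 = 0.5)
  starts <- list()
  # start 1: crude rates per arm (one-step) or the two-phase heuristic
  s1 <- if (spec$structure == "two-step") two_step_seed(obs) else
    c(lnA1 = seed$lnA, Ea1 = seed$Ea,
      lnA2 = seed$lnA - 1.5, Ea2 = min(2.8e5, seed$Ea + 3e4), base)
  starts[[1]] <- s1
  # grid starts: Ea x k(40 degC) targets
  grid <- expand.grid(Ea = c(5e4, 8e4, 1.1e5, 1.4e5), k40 = c(1e-3, 3e-2))
  for (i in seq_len(nrow(grid))) {
    Ea <- grid$Ea[i]
    lnA <- log(grid$k40[i]) + Ea / (R_GAS * 313.15)
    s <- c(lnA1 = lnA, Ea1 = Ea, lnA2 = lnA - 2, Ea2 = min(2.8e5, Ea + 4e4), mids)
    if (spec$structure == "two-step") {
      s[["lnA1"]] <- log(grid$k40[i] * 10) + 4e4 / (R_GAS * 313.15)
      s[["Ea1"]] <- 4e4
      s[["m1"]] <- 0.05; s[["m2"]] <- 0.05
      s[["n1"]] <- 1; s[["n2"]] <- 1
      s[["v"]] <- 0.4
    }
    starts[[length(starts) + 1]] <- s
  }
  lapply(starts[seq_len(min(n_starts, length(starts)))],
         function(s) s[spec$free])
}

information_criteria <- function(RSS, N, K) {
  rss_eff <- max(RSS, 1e-30) # guard log(0) on noiseless data
  aic <- N * log(rss_eff / N) + 2 * (K + 1)
  list(AIC = aic,
       AICc = aic + 2 * (K + 1) * (K + 2) / (N - K - 2),
       BIC = N * log(rss_eff / N) + (K + 1) * log(N))
}

#' Fit a kinetic model to extent observations
#'
#' Minimizes the residual sum of squares between observed and modeled extent
#' over all isothermal arms simultaneously, using Levenberg-Marquardt with
#' box bounds and a deterministic multi-start strategy (one data-driven
#' Arrhenius seed plus a coarse grid over activation energy and the rate
#' constant at 40 degC). The best start by RSS wins; ties go to the start
#' that converged in fewer iterations.
#'
#' Information criteria use the least-squares forms with the error variance
#' counted as a parameter: \eqn{AIC = N \ln(RSS/N) + 2(K+1)},
#' \eqn{AICc = AIC + 2(K+1)(K+2)/(N-K-2)},
#' \eqn{BIC = N \ln(RSS/N) + (K+1)\ln N}.
#'
#' @param spec a [model_spec].
#' @param data extent observations as returned by [to_extent()]: columns
#'   \code{time}, \code{temp_K}, \code{alpha}, \code{C}.
#' @param n_starts number of optimizer starts (default 8).
#' @param start optional named start values for the free parameters; when
#'   given, it is used as the only start (warm start).
#' @param weights optional per-observation weights (default unweighted).
#' @param alpha0 initial sub-extent regularization.
#' @param maxiter Levenberg-Marquardt iteration cap per start (default 300).
#' @param rtol,atol integrator tolerances used inside the objective.
#' @return Object of class \code{"kinetic_fit"} with elements \code{spec},
#'   \code{params}, \code{estimate}, \code{RSS}, \code{N}, \code{K},
#'   \code{fitted}, \code{residuals}, \code{converged}, \code{niter},
#'   \code{AIC}, \code{AICc}, \code{BIC} and the data fitted.
#' @export
fit_model <- function(spec, data, n_starts = 8, start = NULL, weights = NULL,
                      alpha0 = 1e-8, maxiter = 300, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  req <- c("time", "temp_K", "alpha", "C")
  if (!all(req %in% names(data)))
    stop("extent observations need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  obs <- data
  N <- nrow(obs)
  K <- spec$K
  if (N <= K + 2)
    stop(sprintf("N = %d observations cannot support K = %d free parameters (AICc needs N > K + 2)",
                 N, K), call. = FALSE)
  w <- if (is.null(weights)) rep(1, N) else sqrt(weights)
  lower <- vapply(spec$bounds, `[`, 0, 1)
  upper <- vapply(spec$bounds, `[`, 0, 2)
  resid_fun <- function(free_vals) {
    names(free_vals) <- spec$free
    pv <- spec_full_params(spec, free_vals)
    (alpha_model_at(pv, obs, alpha0, rtol, atol) - obs$alpha) * w
  }
  starts <- if (!is.null(start)) list(clamp_start(start[spec$free], lower, upper))
            else make_starts(spec, obs, n_starts)
  best <- NULL
  for (s in starts) {
    s <- clamp_start(unlist(s), lower, upper)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, maxfev = 100 * maxiter,
                             ftol = 1e-9, ptol = 1e-9))),
      error = function(e) NULL)
    if (is.null(res)) next
    cand <- list(par = res$par, rss = res$deviance, info = res$info,
                 niter = res$niter)
    if (is.null(best) || cand$rss < best$rss - 1e-15 ||
        (abs(cand$rss - best$rss) <= 1e-15 && cand$niter < best$niter))
      best <- cand
  }
  if (is.null(best))
    stop("all optimizer starts diverged; no fit available", call. = FALSE)
  est <- unlist(best$par)
  names(est) <- spec$free
  pv <- spec_full_params(spec, est)
  fitted_alpha <- alpha_model_at(pv, obs, alpha0, rtol, atol)
  residuals <- obs$alpha - fitted_alpha
  RSS <- sum((residuals * w)^2)
  ic <- information_criteria(RSS, N, K)
  structure(list(spec = spec, params = as_kinetic_params(pv), estimate = est,
                 RSS = RSS, N = N, K = K,
                 fitted = fitted_alpha, residuals = residuals,
                 converged = best$info %in% 1:4, info = best$info,
                 niter = best$niter,
                 AIC = ic$AIC, AICc = ic$AICc, BIC = ic$BIC,
                 data = obs, alpha0 = alpha0, weights = weights),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit '%s': RSS = %.4g, N = %d, K = %d, AICc = %.2f, BIC = %.2f%s\n",
              x$spec$name, x$RSS, x$N, x$K, x$AICc, x$BIC,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' Predict from a kinetic fit over any temperature program
#'
#' @param fit a [fit_model()] result.
#' @param profile a [temperature_profile].
#' @param times output grid (days).
#' @param C concentration covariate.
#' @param transform optional [attribute_transform]; when given the returned
#'   curve carries a \code{value} column in attribute units.
#' @return An [integrate_extent()] curve.
#' @export
predict_fit <- function(fit, profile, times, C = 1, transform = NULL) {
  curve <- integrate_extent(fit$params, profile, times, C = C,
                            alpha0 = fit$alpha0)
  if (!is.null(transform)) curve <- predict_attribute(curve, transform)
  curve
}

#' Serialize a fit to JSON
#'
#' @param fit a [kinetic_fit].
#' @param path optional output file.
#' @return JSON text.
#' @export
fit_to_json <- function(fit, path = NULL) {
  doc <- list(model = fit$spec$name, structure = fit$spec$structure,
              params = as.list(unclass(fit$params)),
              estimate = as.list(fit$estimate),
              RSS = fit$RSS, N = fit$N, K = fit$K,
              AIC = fit$AIC, AICc = fit$AICc, BIC = fit$BIC,
              converged = fit$converged)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Joint fit across protein concentrations with a free concentration exponent
#'
#' Fits a single parameter vector (including the exponent p) across all
#' concentration arms, the degradation rate scaling as \eqn{C^p}.
#'
#' @param spec a [model_spec] with at least one concentration exponent free.
#' @param data extent observations carrying the \code{C} covariate, or a list
#'   of such data.frames (one per concentration) which are pooled.
#' @param ... passed to [fit_model()].
#' @return A [kinetic_fit].
#' @export
fit_concentration_dependent <- function(spec, data, ...) {
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  p_free <- intersect(c("p1", "p2"), spec$free)
  if (length(p_free) == 0)
    stop("spec has no free concentration exponent; use fit_model()", call. = FALSE)
  if (anyNA(data$C))
    stop("concentration must be recorded for every observation", call. = FALSE)
  if (length(unique(data$C)) < 2)
    stop("a free concentration exponent is not identifiable from a single concentration",
         call. = FALSE)
  fit_model(spec, data, ...)
}

#' Temperature-range robustness of a fit
#'
#' Refits the model on data restricted to each temperature interval and
#' reports relative parameter differences against the full-data fit. The
#' same parameters should be recovered on e.g. 5-40 degC and 5-25 degC when
#' a single degradation pathway is active over the whole range.
#'
#' @param spec a [model_spec].
#' @param data extent observations (see [fit_model()]).
#' @param ranges list of c(lo, hi) temperature intervals in degC.
#' @param threshold relative activation-energy difference above which the
#'   verdict becomes "not robust" (default 0.20).
#' @param ... passed to [fit_model()].
#' @return List with the reference fit, per-range fits, a data.frame of
#'   relative deltas and a \code{verdict} ("robust"/"not robust").
#' @export
robustness_check <- function(spec, data, ranges, threshold = 0.20, ...) {
  ref <- fit_model(spec, data, ...)
  ea_names <- intersect(c("Ea1", "Ea2"), spec$free)
  fits <- list(); deltas <- list()
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    keep <- data$temp_K >= r[1] + 273.15 - 0.05 & data$temp_K <= r[2] + 273.15 + 0.05
    sub <- data[keep, , drop = FALSE]
    lab <- sprintf("%g-%g degC", r[1], r[2])
    if (length(unique(sub$temp_K)) < 2 || nrow(sub) <= spec$K + 2) {
      warning("range ", lab, " leaves too little data; skipped", call. = FALSE)
      next
    }
    f <- fit_model(spec, sub, ...)
    d <- (f$estimate - ref$estimate[names(f$estimate)]) /
      pmax(abs(ref$estimate[names(f$estimate)]), 1e-12)
    fits[[lab]] <- f
    deltas[[lab]] <- data.frame(range = lab, parameter = names(d),
                                reference = unname(ref$estimate[names(d)]),
                                refit = unname(f$estimate),
                                rel_delta = unname(d))
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else
    data.frame(range = character(), parameter = character(),
               reference = numeric(), refit = numeric(), rel_delta = numeric())
  ea_dev <- deltas$rel_delta[deltas$parameter %in% ea_names]
  verdict <- if (length(ea_dev) == 0 || all(abs(ea_dev) <= threshold))
    "robust" else "not robust"
  list(reference = ref, fits = fits, deltas = deltas,
       threshold = threshold, verdict = verdict)
}
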