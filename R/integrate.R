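#' Integrate the kinetic system over a temperature program
#'
#' Solves the two coupled sub-extent ODEs \eqn{d\alpha_i/dt = k_i(T(t))
#' (1-\alpha_i)^{n_i} \alpha_i^{m_i} C^{p_i}} and reports the observed extent
#' \eqn{\alpha = v\alpha_1 + (1-v)\alpha_2} on a user grid. Non-autocatalytic
#' isothermal segments are propagated by their closed forms; everything else
#' uses an adaptive embedded Runge-Kutta 4(5) scheme.
#'
#' @param params a [kinetic_params] vector.
#' @param profile a [temperature_profile]; the grid must lie in its domain.
#' @param times increasing grid (days); the first element is the start of the
#'   integration.
#' @param C protein concentration covariate (constant during integration).
#' @param alpha0 initial sub-extent of each step. The default 1e-8 is the
#'   standard thermokinetic regularization that lets autocatalytic steps
#'   (m > 0) leave the \eqn{\alpha = 0} fixed point.
#' @param rtol,atol solver tolerances.
#' @return Object of class \code{"extent_curve"}: a data.frame with columns
#'   \code{time}, \code{temp_K}, \code{alpha1}, \code{alpha2}, \code{alpha}.
#' @examples
#' p <- kinetic_params(lnA1 = log(0.05), Ea1 = 0, n1 = 1)
#' integrate_extent(p, constant_profile(25), times = c(0, 10))
#' @export
integrate_extent <- function(params, profile, times, C = 1, alpha0 = 1e-8,
                             rtol = 1e-8, atol = 1e-10) {
  p <- as_kinetic_params(params)
  stopifnot(inherits(profile, "temperature_profile"))
  times <- as.numeric(times)
  if (length(times) < 1) stop("empty time grid", call. = FALSE)
  if (any(diff(times) < 0)) stop("time grid must be non-decreasing", call. = FALSE)
  if (times[1] < profile$time[1] - 1e-12)
    stop("grid starts before the profile domain", call. = FALSE)
  if ((p[["p1"]] != 0 || p[["p2"]] != 0) && C <= 0)
    stop("C must be positive when a concentration exponent is non-zero",
         call. = FALSE)
  interp <- if (profile$interpolation == "step") 1L else 0L
  v <- p[["v"]]
  sub <- function(lnA, Ea, n, m, pw) {
    substep_alpha_cpp(times, alpha0, lnA + pw * log(C), Ea, n, m,
                      profile$time, profile$temp_K, interp, rtol, atol)
  }
  a1 <- if (v > 0) sub(p[["lnA1"]], p[["Ea1"]], p[["n1"]], p[["m1"]], p[["p1"]]) else rep(alpha0, length(times))
  a2 <- if (v < 1) sub(p[["lnA2"]], p[["Ea2"]], p[["n2"]], p[["m2"]], p[["p2"]]) else rep(alpha0, length(times))
  out <- data.frame(time = times,
                    temp_K = temperature_at(profile, times),
                    alpha1 = a1, alpha2 = a2,
                    alpha = v * a1 + (1 - v) * a2)
  attr(out, "params") <- p
  attr(out, "C") <- C
  attr(out, "alpha0") <- alpha0
  class(out) <- c("extent_curve", "data.frame")
  out
}

#' Map measured attribute values to/from degradation extent
#'
#' Observed attributes (HMW %, potency, titer, ...) are linear in the extent:
#' \eqn{y = y_0 + direction \cdot span \cdot \alpha}. \code{direction = +1}
#' for attributes that grow with degradation (impurities, HMW), \code{-1} for
#' those that fall (potency, monomer content).
#'
#' @param y0 baseline attribute value (value at alpha = 0).
#' @param span total conversion span in attribute units (> 0).
#' @param direction +1 or -1.
#' @param name,unit optional attribute metadata.
#' @return Object of class \code{"attribute_transform"}.
#' @export
attribute_transform <- function(y0, span, direction = c(1, -1),
                                name = "attribute", unit = "") {
  direction <- direction[1]
  if (!direction %in% c(1, -1)) stop("direction must be +1 or -1", call. = FALSE)
  if (!is.finite(span) || span <= 0) stop("span must be positive", call. = FALSE)
  structure(list(y0 = y0, span = span, direction = direction,
                 name = name, unit = unit),
            class = "attribute_transform")
}

#' @export
print.attribute_transform <- function(x, ...) {
  cat(sprintf("Attribute '%s' (%s): y0 = %g, span = %g, %s with degradation\n",
              x$name, x$unit, x$y0, x$span,
              if (x$direction > 0) "increasing" else "decreasing"))
  invisible(x)
}

#' Convert an extent trajectory to attribute units
#'
#' @param curve an [integrate_extent()] result, or a numeric vector of extents.
#' @param transform an [attribute_transform].
#' @return For an extent curve, the data.frame with an added \code{value}
#'   column; for a numeric vector, the attribute values.
#' @export
predict_attribute <- function(curve, transform) {
  stopifnot(inherits(transform, "attribute_transform"))
  f <- function(a) transform$y0 + transform$direction * transform$span * a
  if (is.numeric(curve)) return(f(curve))
  stopifnot(inherits(curve, "extent_curve"))
  curve$value <- f(curve$alpha)
  curve
}

#' Export a trajectory as CSV
#'
#' Columns: \code{time_days, temperature_C, alpha, value}.
#' @param curve an [extent_curve] (with a \code{value} column if a transform
#'   was applied; otherwise \code{value} is left as NA).
#' @param path output file.
#' @export
write_trajectory_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_days = curve$time,
                              temperature_C = curve$temp_K - 273.15,
                              alpha = curve$alpha,
                              value = if (!is.null(curve$value)) curve$value else NA),
                   path, row.names = FALSE)
  invisible(path)
}
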