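#' Piecewise-linear temperature program
#'
#' Represents any storage/shipment temperature history as ordered
#' (time, temperature) knots. Between knots the temperature is linearly
#' interpolated (or held constant with \code{interpolation = "step"}, for
#' chamber programs); beyond the last knot it is extrapolated as constant.
#'
#' @param time_days knot times in days, strictly increasing, at least one.
#' @param temp_C knot temperatures in Celsius (exclusive with \code{temp_K}).
#' @param temp_K knot temperatures in Kelvin.
#' @param interpolation \code{"linear"} or \code{"step"} (left-hold).
#' @return Object of class \code{"temperature_profile"}.
#' @examples
#' temperature_profile(c(0, 1), temp_C = c(5, 25))
#' @export
temperature_profile <- function(time_days, temp_C = NULL, temp_K = NULL,
                                interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (is.null(temp_K)) {
    if (is.null(temp_C)) stop("supply temp_C or temp_K", call. = FALSE)
    temp_K <- temp_C + 273.15
  }
  time_days <- as.numeric(time_days)
  temp_K <- as.numeric(temp_K)
  if (length(time_days) < 1) stop("a profile needs at least one knot", call. = FALSE)
  if (length(time_days) != length(temp_K))
    stop("time and temperature knots differ in length", call. = FALSE)
  if (any(!is.finite(time_days)) || any(!is.finite(temp_K)))
    stop("profile knots must be finite", call. = FALSE)
  if (length(time_days) > 1 && any(diff(time_days) <= 0))
    stop("knot times must be strictly increasing", call. = FALSE)
  if (any(temp_K <= 0)) stop("temperatures must be positive Kelvin", call. = FALSE)
  structure(list(time = time_days, temp_K = temp_K, interpolation = interpolation),
            class = "temperature_profile")
}

#' Isothermal profile helper
#'
#' @param temp_C constant temperature in Celsius.
#' @param t0 start time (days).
#' @return A single-knot [temperature_profile].
#' @export
constant_profile <- function(temp_C, t0 = 0) {
  temperature_profile(t0, temp_C = temp_C)
}

is_isothermal <- function(profile) {
  length(unique(profile$temp_K)) == 1L
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("Temperature profile: %d knot(s), %s interpolation, %.4g-%.4g degC over %.4g d\n",
              length(x$time), x$interpolation,
              min(x$temp_K) - 273.15, max(x$temp_K) - 273.15, diff(range(x$time))))
  invisible(x)
}

#' Evaluate a temperature profile
#'
#' @param profile a [temperature_profile].
#' @param t times in days, each at or after the first knot.
#' @return Temperatures in Kelvin; exact at knots, interpolated between them,
#'   constant beyond the last knot.
#' @export
temperature_at <- function(profile, t) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (any(t < profile$time[1] - 1e-12))
    stop("time before profile start", call. = FALSE)
  if (length(profile$time) == 1L) return(rep(profile$temp_K, length(t)))
  method <- if (profile$interpolation == "step") "constant" else "linear"
  stats::approx(profile$time, profile$temp_K, xout = pmin(t, max(profile$time)),
                method = method, rule = 2, f = 0)$y
}

#' Build a profile from temperature-logger records
#'
#' Converts raw electronic-logger records (elapsed hours, degC) into a
#' [temperature_profile] in internal units. Rows are sorted by time and exact
#' duplicates removed; duplicate timestamps carrying different temperatures
#' are rejected.
#'
#' @param time_hours elapsed hours of each record.
#' @param temp_C recorded temperatures (degC).
#' @param temp_range admissible physical range (degC), default -80..80.
#' @param interpolation passed to [temperature_profile()].
#' @return A [temperature_profile].
#' @export
profile_from_records <- function(time_hours, temp_C, temp_range = c(-80, 80),
                                 interpolation = "linear") {
  if (length(time_hours) < 1) stop("no logger records", call. = FALSE)
  if (any(!is.finite(time_hours)) || any(!is.finite(temp_C)))
    stop("unparseable logger records", call. = FALSE)
  if (any(temp_C < temp_range[1] | temp_C > temp_range[2]))
    stop(sprintf("temperature outside physical range [%g, %g] degC",
                 temp_range[1], temp_range[2]), call. = FALSE)
  ord <- order(time_hours)
  th <- time_hours[ord]; tc <- temp_C[ord]
  keep <- !duplicated(data.frame(th, tc))
  th <- th[keep]; tc <- tc[keep]
  if (anyDuplicated(th))
    stop("duplicate timestamps with differing temperatures", call. = FALSE)
  temperature_profile(th / 24, temp_C = tc, interpolation = interpolation)
}

#' Read a temperature-logger CSV
#'
#' Expects a header with columns \code{time} and \code{temperature_C}. The
#' time column may hold numeric elapsed hours or ISO-8601 timestamps
#' (auto-detected; override with \code{time_format}).
#'
#' @param path CSV file.
#' @param time_format \code{"auto"}, \code{"hours"} or \code{"iso8601"}.
#' @param ... passed to [profile_from_records()].
#' @return A [temperature_profile].
#' @export
read_temperature_csv <- function(path, time_format = c("auto", "hours", "iso8601"),
                                 ...) {
  time_format <- match.arg(time_format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "temperature_C")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("logger CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 1) stop("empty logger CSV", call. = FALSE)
  raw <- df$time
  numeric_ok <- !anyNA(suppressWarnings(as.numeric(raw)))
  if (time_format == "hours" || (time_format == "auto" && numeric_ok)) {
    hours <- as.numeric(raw)
  } else {
    ts <- as.POSIXct(raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
    if (anyNA(ts)) stop("unparseable timestamps in logger CSV", call. = FALSE)
    hours <- as.numeric(difftime(ts, ts[1], units = "hours"))
  }
  profile_from_records(hours, as.numeric(df$temperature_C), ...)
}

#' Write a profile to logger CSV format
#'
#' @param profile a [temperature_profile].
#' @param path output CSV (columns \code{time} in elapsed hours,
#'   \code{temperature_C}).
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(time = profile$time * 24,
                              temperature_C = profile$temp_K - 273.15),
                   path, row.names = FALSE)
  invisible(path)
}
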