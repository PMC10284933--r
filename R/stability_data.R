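#' Accelerated-stability dataset
#'
#' One record per (time, incubation temperature, measured value), optionally
#' carrying protein concentration and batch label. Temperatures are grouped
#' into study arms by value after rounding to 0.1 degC.
#'
#' @param time_days pull-point times (days, >= 0).
#' @param temp_C incubation temperatures (degC).
#' @param value measured attribute values.
#' @param concentration optional protein concentration (mg/mL) per record.
#' @param batch optional batch labels.
#' @param attribute attribute name.
#' @param unit attribute unit.
#' @param direction +1 if the attribute grows with degradation, -1 if it falls.
#' @return Object of class \code{"stability_dataset"} (a data.frame).
#' @export
stability_dataset <- function(time_days, temp_C, value, concentration = NA,
                              batch = NA, attribute = "attribute", unit = "",
                              direction = 1) {
  time_days <- as.numeric(time_days)
  if (any(!is.finite(time_days)) || any(time_days < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(temp_C))) stop("temperatures must be finite", call. = FALSE)
  if (anyNA(value)) stop("NA attribute values are not allowed", call. = FALSE)
  ds <- data.frame(time_days = time_days, temp_C = as.numeric(temp_C),
                   value = as.numeric(value),
                   concentration = concentration, batch = batch)
  attr(ds, "attribute") <- list(name = attribute, unit = unit,
                                direction = direction)
  class(ds) <- c("stability_dataset", "data.frame")
  ds
}

#' @export
print.stability_dataset <- function(x, ...) {
  a <- attr(x, "attribute")
  cat(sprintf("Stability dataset: %d records, arms {%s} degC, attribute '%s'%s\n",
              nrow(x), paste(arms(x), collapse = ", "), a$name,
              if (nzchar(a$unit)) paste0(" (", a$unit, ")") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Temperature arms of a dataset
#'
#' @param ds a [stability_dataset].
#' @return Sorted unique arm temperatures (degC, rounded to 0.1).
#' @export
arms <- function(ds) {
  sort(unique(round(ds$temp_C, 1)))
}

#' Read an accelerated-stability CSV
#'
#' Required columns: \code{time_days} (or \code{time_months}, converted at
#' 30.4375 days/month), \code{temperature_C}, \code{value}. Optional:
#' \code{concentration_mg_ml}, \code{batch}.
#'
#' @param path CSV file (comma-separated, header row, UTF-8).
#' @param attribute,unit attribute metadata.
#' @param direction +1 (attribute increases with degradation) or -1.
#' @return A [stability_dataset].
#' @export
read_stability_csv <- function(path, attribute = "attribute", unit = "",
                               direction = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_days <- "time_days" %in% names(df)
  has_months <- "time_months" %in% names(df)
  if (!has_days && !has_months)
    stop("stability CSV missing column 'time_days' (or 'time_months')",
         call. = FALSE)
  for (col in c("temperature_C", "value"))
    if (!col %in% names(df))
      stop("stability CSV missing column '", col, "'", call. = FALSE)
  tm <- if (has_days) as.numeric(df$time_days) else
    as.numeric(df$time_months) * DAYS_PER_MONTH
  bad <- which(!is.finite(tm) | !is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop("unparseable numbers in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stability_dataset(tm, as.numeric(df$temperature_C), as.numeric(df$value),
                    concentration = if ("concentration_mg_ml" %in% names(df))
                      as.numeric(df$concentration_mg_ml) else NA,
                    batch = if ("batch" %in% names(df)) df$batch else NA,
                    attribute = attribute, unit = unit, direction = direction)
}

#' Write a stability dataset to CSV
#'
#' @param ds a [stability_dataset].
#' @param path output file.
#' @export
write_stability_csv <- function(ds, path) {
  out <- data.frame(time_days = ds$time_days, temperature_C = ds$temp_C,
                    value = ds$value)
  if (!all(is.na(ds$concentration))) out$concentration_mg_ml <- ds$concentration
  if (!all(is.na(ds$batch))) out$batch <- ds$batch
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Baseline attribute value of a dataset
#'
#' Mean of the time-zero replicates (or of the earliest pull point when no
#' exact time-zero record exists).
#' @param ds a [stability_dataset].
#' @return Numeric baseline y0.
#' @export
baseline_y0 <- function(ds) {
  t0 <- min(ds$time_days)
  mean(ds$value[ds$time_days == t0])
}

#' Convert measured values to degradation-extent observations
#'
#' \eqn{\alpha = direction (y - y_0)/span}. Values slightly outside [0, 1]
#' due to assay noise are retained (not clipped) so that least squares sees
#' the raw information.
#'
#' @param ds a [stability_dataset].
#' @param transform an [attribute_transform].
#' @return data.frame with columns \code{time} (days), \code{temp_K},
#'   \code{alpha} and \code{C} (concentration covariate, 1 when unrecorded).
#' @export
to_extent <- function(ds, transform) {
  stopifnot(inherits(ds, "stability_dataset"),
            inherits(transform, "attribute_transform"))
  data.frame(time = ds$time_days,
             temp_K = round(ds$temp_C, 1) + 273.15,
             alpha = transform$direction * (ds$value - transform$y0) / transform$span,
             C = ifelse(is.na(ds$concentration), 1, ds$concentration))
}

#' Stage-1 design validation for accelerated-stability studies
#'
#' Checks a dataset against the good-modeling-practice design rules: at least
#' \code{min_arms} incubation temperatures, at least \code{min_points} data
#' points (warning below \code{good_points}), and at least
#' \code{min_hot_extent} degradation reached at the hottest arm.
#'
#' @param ds a [stability_dataset].
#' @param transform an [attribute_transform] used to express observed
#'   degradation as extent of conversion.
#' @param min_arms minimum number of temperature arms (default 3).
#' @param min_points hard minimum number of records (default 20).
#' @param good_points preferred minimum (default 30; below it a warning).
#' @param min_hot_extent minimum extent reached at the hottest arm (0.20).
#' @return Object of class \code{"design_report"}: per-rule observations and
#'   an overall status \code{"pass"}, \code{"warn"} or \code{"fail"}.
#' @export
validate_design <- function(ds, transform, min_arms = 3, min_points = 20,
                            good_points = 30, min_hot_extent = 0.20) {
  stopifnot(inherits(ds, "stability_dataset"))
  if (nrow(ds) == 0) stop("empty dataset", call. = FALSE)
  a <- arms(ds)
  n <- nrow(ds)
  ext <- to_extent(ds, transform)
  hot <- max(a)
  hot_extent <- max(ext$alpha[round(ds$temp_C, 1) == hot])
  checks <- data.frame(
    rule = c("temperature arms", "data points", "preferred data points",
             "hot-arm degradation extent"),
    observed = c(length(a), n, n, hot_extent),
    threshold = c(min_arms, min_points, good_points, min_hot_extent),
    status = c(if (length(a) >= min_arms) "pass" else "fail",
               if (n >= min_points) "pass" else "fail",
               if (n >= good_points) "pass" else "warn",
               if (hot_extent >= min_hot_extent) "pass" else "fail"),
    stringsAsFactors = FALSE)
  overall <- if (any(checks$status == "fail")) "fail"
             else if (any(checks$status == "warn")) "warn" else "pass"
  structure(list(checks = checks, status = overall, hottest_arm_C = hot),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Study-design validation:", toupper(x$status), "\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s: observed %.4g (threshold %.4g)\n",
                x$checks$status[i], x$checks$rule[i],
                x$checks$observed[i], x$checks$threshold[i]))
  invisible(x)
}
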