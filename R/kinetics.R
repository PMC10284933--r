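#' @useDynLib stabkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Universal gas constant (J mol-1 K-1)
#'
#' Module constant used by every Arrhenius evaluation in the package.
#' @export
R_GAS <- 8.314462618

#' Days per calendar month used at the I/O boundary
#'
#' Stability protocols report pull points in months; internally all times are
#' days. One month is taken as 365.25/12 = 30.4375 days.
#' @export
DAYS_PER_MONTH <- 30.4375

# canonical parameter order of the two-step rate law
PARAM_NAMES <- c("lnA1", "Ea1", "n1", "m1", "lnA2", "Ea2", "n2", "m2",
                 "v", "p1", "p2")

#' Kinetic parameters of the two-step competitive rate law
#'
#' The observed degradation rate is a weighted sum of two independent
#' single-step reactions,
#' \deqn{d\alpha/dt = v k_1(T) (1-\alpha_1)^{n_1} \alpha_1^{m_1} C^{p_1}
#'   + (1-v) k_2(T) (1-\alpha_2)^{n_2} \alpha_2^{m_2} C^{p_2}}
#' with Arrhenius rate constants \eqn{k_i(T) = A_i \exp(-Ea_i / RT)}.
#' Setting \code{v = 1} reduces the model to a single step; \code{m = 0}
#' removes the autocatalytic contribution of a step.
#'
#' @param lnA1,lnA2 natural log of the pre-exponential factors (per day).
#' @param Ea1,Ea2 activation energies (J/mol), non-negative.
#' @param n1,n2 reaction orders (dimensionless, >= 0).
#' @param m1,m2 autocatalytic exponents (dimensionless, >= 0).
#' @param v contribution ratio of step 1, in [0, 1].
#' @param p1,p2 protein-concentration exponents (dimensionless).
#' @return A named numeric vector of class \code{"kinetic_params"}.
#' @examples
#' kinetic_params(lnA1 = 26, Ea1 = 8e4, n1 = 1)
#' @export
kinetic_params <- function(lnA1 = 0, Ea1 = 0, n1 = 0, m1 = 0,
                           lnA2 = 0, Ea2 = 0, n2 = 0, m2 = 0,
                           v = 1, p1 = 0, p2 = 0) {
  p <- c(lnA1 = lnA1, Ea1 = Ea1, n1 = n1, m1 = m1,
         lnA2 = lnA2, Ea2 = Ea2, n2 = n2, m2 = m2,
         v = v, p1 = p1, p2 = p2)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  stopifnot(is.numeric(p), all(PARAM_NAMES %in% names(p)))
  if (any(!is.finite(p[PARAM_NAMES])))
    stop("kinetic parameters must be finite", call. = FALSE)
  if (p[["v"]] < 0 || p[["v"]] > 1)
    stop("v must lie in [0, 1]", call. = FALSE)
  if (p[["Ea1"]] < 0 || p[["Ea2"]] < 0)
    stop("activation energies must be >= 0", call. = FALSE)
  if (p[["m1"]] < 0 || p[["m2"]] < 0)
    stop("autocatalytic exponents m must be >= 0", call. = FALSE)
  if (p[["n1"]] < 0 || p[["n2"]] < 0)
    stop("reaction orders n must be >= 0", call. = FALSE)
  invisible(p)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  do.call(kinetic_params, as.list(x[PARAM_NAMES]))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-step kinetic parameters (v =", signif(x[["v"]], 4), ")\n")
  cat(sprintf("  step 1: lnA = %.4g, Ea = %.4g kJ/mol, n = %.3g, m = %.3g, p = %.3g\n",
              x[["lnA1"]], x[["Ea1"]] / 1000, x[["n1"]], x[["m1"]], x[["p1"]]))
  if (x[["v"]] < 1)
    cat(sprintf("  step 2: lnA = %.4g, Ea = %.4g kJ/mol, n = %.3g, m = %.3g, p = %.3g\n",
                x[["lnA2"]], x[["Ea2"]] / 1000, x[["n2"]], x[["m2"]], x[["p2"]]))
  invisible(x)
}

#' Arrhenius rate constant
#'
#' \eqn{k(T) = \exp(lnA - Ea / (R T))}, in 1/day when \code{lnA} is the log of
#' a per-day pre-exponential factor.
#'
#' @param lnA natural log of the pre-exponential factor.
#' @param Ea activation energy (J/mol).
#' @param T_K absolute temperature (K), must be positive.
#' @return Rate constant(s), per day. Vectorized over all arguments.
#' @examples
#' arrhenius_k(26.1, 8e4, 298.15)
#' @export
arrhenius_k <- function(lnA, Ea, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  exp(lnA - Ea / (R_GAS * T_K))
}

#' Instantaneous degradation rate of the two-step rate law
#'
#' Evaluates the rate law at given sub-extents, temperature and protein
#' concentration. The observed rate is \code{v * r1 + (1 - v) * r2} where
#' \code{r_i} is the rate of step i at its own sub-extent.
#'
#' @param params a [kinetic_params] vector.
#' @param alpha1,alpha2 sub-extents of steps 1 and 2, each in [0, 1].
#' @param T_K absolute temperature (K).
#' @param C protein concentration at the start of the reaction (covariate;
#'   must be positive whenever a concentration exponent p is non-zero).
#' @return A list with components \code{dalpha1}, \code{dalpha2} (step rates)
#'   and \code{dalpha} (observed rate), all per day and non-negative.
#' @export
extent_rate <- function(params, alpha1, alpha2 = alpha1, T_K, C = 1) {
  p <- as_kinetic_params(params)
  if (any(alpha1 < 0 | alpha1 > 1) || any(alpha2 < 0 | alpha2 > 1))
    stop("extents must lie in [0, 1]", call. = FALSE)
  if ((p[["p1"]] != 0 || p[["p2"]] != 0) && any(C <= 0))
    stop("C must be positive when a concentration exponent is non-zero",
         call. = FALSE)
  step_rate <- function(lnA, Ea, n, m, pw, a) {
    k <- arrhenius_k(lnA, Ea, T_K) * C^pw
    f <- rep(1, length(a))
    if (n != 0) f <- f * (1 - a)^n
    if (m != 0) f <- f * a^m
    k * f
  }
  r1 <- step_rate(p[["lnA1"]], p[["Ea1"]], p[["n1"]], p[["m1"]], p[["p1"]], alpha1)
  r2 <- step_rate(p[["lnA2"]], p[["Ea2"]], p[["n2"]], p[["m2"]], p[["p2"]], alpha2)
  list(dalpha1 = r1, dalpha2 = r2,
       dalpha = p[["v"]] * r1 + (1 - p[["v"]]) * r2)
}

#' Bounds used by default for fitted parameters
#'
#' @return Named list of c(lower, upper) pairs, one per rate-law parameter.
#' @export
default_bounds <- function() {
  list(lnA1 = c(-20, 130), Ea1 = c(1e4, 3e5), n1 = c(0, 3), m1 = c(0, 2),
       lnA2 = c(-20, 130), Ea2 = c(1e4, 3e5), n2 = c(0, 3), m2 = c(0, 2),
       v = c(0, 1), p1 = c(-2, 3), p2 = c(-2, 3))
}

#' Define a candidate kinetic model for screening
#'
#' A model specification partitions the rate-law parameters into fixed values
#' and free (fitted) parameters with finite box bounds.
#'
#' @param name short label for the model.
#' @param structure \code{"one-step"} or \code{"two-step"}.
#' @param fixed named numeric vector of parameters held at fixed values.
#' @param free character vector of parameter names to fit (K >= 1).
#' @param bounds named list of c(lo, hi) for free parameters; missing entries
#'   fall back to [default_bounds()].
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(name, structure = c("one-step", "two-step"),
                       fixed = c(), free, bounds = list()) {
  structure <- match.arg(structure)
  free <- as.character(free)
  if (length(free) < 1) stop("a model needs at least one free parameter", call. = FALSE)
  if (anyDuplicated(c(names(fixed), free)))
    stop("parameters cannot be both fixed and free", call. = FALSE)
  missing_p <- setdiff(PARAM_NAMES, c(names(fixed), free))
  if (length(missing_p))
    stop("unassigned parameters: ", paste(missing_p, collapse = ", "), call. = FALSE)
  db <- default_bounds()
  b <- lapply(free, function(nm) {
    bi <- if (!is.null(bounds[[nm]])) bounds[[nm]] else db[[nm]]
    if (length(bi) != 2 || any(!is.finite(bi)) || bi[1] >= bi[2])
      stop("invalid bounds for ", nm, call. = FALSE)
    bi
  })
  names(b) <- free
  structure(list(name = name, structure = structure,
                 fixed = unlist(fixed)[names(fixed)], free = free, bounds = b,
                 K = length(free)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s' (%s), K = %d free: %s\n", x$name, x$structure,
              x$K, paste(x$free, collapse = ", ")))
  invisible(x)
}

spec_full_params <- function(spec, free_values) {
  p <- stats::setNames(numeric(length(PARAM_NAMES)), PARAM_NAMES)
  p["v"] <- 1
  p[names(spec$fixed)] <- spec$fixed
  p[spec$free] <- free_values
  p
}

one_step_fixed <- function(extra = c()) {
  base <- c(lnA2 = 0, Ea2 = 1e4, n2 = 1, m2 = 0, v = 1, p1 = 0, p2 = 0)
  base[names(extra)] <- extra
  base
}

#' Default model catalog for kinetic screening
#'
#' The catalog spans the standard phenomenological forms screened in
#' accelerated-stability practice: zero-order, first-order, nth-order,
#' autocatalytic (Prout-Tompkins type) and the competitive two-step model.
#' Concentration exponents are fixed at zero unless
#' \code{concentration_dependent = TRUE}, which frees p (step 1, plus step 2
#' for the two-step entry).
#'
#' @param concentration_dependent free the concentration exponent(s)?
#' @return List of [model_spec] objects, simplest first.
#' @export
default_model_catalog <- function(concentration_dependent = FALSE) {
  pfree <- function(free, two = FALSE) {
    if (!concentration_dependent) return(free)
    c(free, if (two) c("p1", "p2") else "p1")
  }
  pfix <- function(fx, two = FALSE) {
    if (!concentration_dependent) return(fx)
    fx[setdiff(names(fx), if (two) c("p1", "p2") else "p1")]
  }
  cat <- list(
    model_spec("zero-order", "one-step",
               fixed = pfix(one_step_fixed(c(n1 = 0, m1 = 0))),
               free = pfree(c("lnA1", "Ea1"))),
    model_spec("first-order", "one-step",
               fixed = pfix(one_step_fixed(c(n1 = 1, m1 = 0))),
               free = pfree(c("lnA1", "Ea1"))),
    model_spec("nth-order", "one-step",
               fixed = pfix(one_step_fixed(c(m1 = 0))),
               free = pfree(c("lnA1", "Ea1", "n1"))),
    model_spec("autocatalytic", "one-step",
               fixed = pfix(one_step_fixed()),
               free = pfree(c("lnA1", "Ea1", "n1", "m1"))),
    model_spec("two-step", "two-step",
               fixed = pfix(c(p1 = 0, p2 = 0), two = TRUE),
               free = pfree(c("lnA1", "Ea1", "n1", "m1",
                              "lnA2", "Ea2", "n2", "m2", "v"), two = TRUE))
  )
  names(cat) <- vapply(cat, `[[`, "", "name")
  cat
}

#' Serialize a model catalog to JSON
#'
#' @param catalog list of [model_spec] objects.
#' @param path optional file to write; when NULL the JSON string is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  doc <- lapply(catalog, function(s) {
    list(name = s$name, structure = s$structure,
         fixed = as.list(s$fixed), free = s$free, bounds = s$bounds)
  })
  txt <- jsonlite::toJSON(unname(doc), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a model catalog from JSON
#'
#' @param path file path or a JSON string produced by [catalog_to_json()].
#' @return List of [model_spec] objects.
#' @export
catalog_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cat <- lapply(doc, function(d) {
    model_spec(d$name, d$structure,
               fixed = unlist(d$fixed), free = unlist(d$free),
               bounds = lapply(d$bounds, unlist))
  })
  names(cat) <- vapply(cat, `[[`, "", "name")
  cat
}
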