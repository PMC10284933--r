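# Shared fixtures: small synthetic designs built in code.

# noiseless first-order extent observations over the standard 5/25/40 design
make_first_order_obs <- function(lnA = 26, Ea = 8e4,
                                 arms_C = c(5, 25, 40),
                                 times_days = c(0, 7.6, 15.2, 30.4, 60.9, 91.3, 182.6),
                                 sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- do.call(rbind, lapply(arms_C, function(Ta) {
    k <- arrhenius_k(lnA, Ea, Ta + 273.15)
    data.frame(time = times_days, temp_K = Ta + 273.15,
               alpha = 1 - exp(-k * times_days), C = 1)
  }))
  if (sigma > 0) obs$alpha <- obs$alpha + stats::rnorm(nrow(obs), 0, sigma)
  obs
}

# one-step catalog (cheap screening in tests that do not need the two-step)
one_step_catalog <- function() {
  default_model_catalog()[c("zero-order", "first-order", "nth-order")]
}

first_order_spec <- function() default_model_catalog()[["first-order"]]

# quick ranking + band for prediction-level tests
quick_band <- function(seed = 1, B = 120, sigma = 0.01, level = 0.95, ...) {
  obs <- make_first_order_obs(sigma = sigma, seed = seed)
  ranking <- screen_models(list(first_order_spec()), obs, n_starts = 2)
  tr <- attribute_transform(y0 = 100, span = 100, direction = -1,
                            name = "potency", unit = "%")
  residual_bootstrap(ranking, profile = constant_profile(5), transform = tr,
                     B = B, level = level, seed = seed, ...)
}
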