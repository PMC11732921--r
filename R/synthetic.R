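# Synthetic anthropometric cohorts with the statistical structure the
# estimation method assumes: a pooled-sex sample aged 0-20 with a
# birth-heavy age distribution, a monotone growth curve with
# age-heteroscedastic stature noise, and measurements derived by inverting
# per-measurement generative curves (saturating for lengths, sigmoid for
# breadths) with multiplicative noise.

#' Default generative measurement curves
#'
#' One generative [stature_model()] per measurement, used by
#' [simulate_cohort()] to derive measurements from simulated statures.
#' Defaults are the registry's nonlinear coefficients, with four synthetic
#' substitutions so every curve is anatomically plausible: the two
#' sanity-flagged registry entries get family-plausible rate constants
#' (tibia midshaft `c = 0.17`, radius proximal `c = 0.21`), and the two
#' measurements whose nonlinear models never converged (tibia and radius
#' distal breadth) get synthetic logistic curves calibrated against their
#' linear registry models. These are generator choices, not corrections to
#' the published coefficients.
#'
#' @return Named list of [stature_model()] objects keyed by canonical
#'   column name.
#' @export
generative_measurement_specs <- function() {
  reg <- load_registry()
  nl <- reg[reg$family != "linear", , drop = FALSE]
  specs <- setNames(nl$model, paste0(nl$bone, "_", nl$measurement, "_mm"))
  # family-plausible rate constants in place of the flagged printed ones
  specs$tibia_midshaft_breadth_mm <- stature_model(
    "tibia", "midshaft_breadth", "logistic3", c(a = 206, b = 10.1, c = 0.17),
    source = "fitted")
  specs$radius_proximal_breadth_mm <- stature_model(
    "radius", "proximal_breadth", "logistic3", c(a = 196, b = 11.6, c = 0.21),
    source = "fitted")
  # synthetic sigmoids for the two measurements with no published nonlinear
  # model, calibrated to track their linear registry models at adult sizes
  specs$tibia_distal_breadth_mm <- stature_model(
    "tibia", "distal_breadth", "logistic3", c(a = 210, b = 9, c = 0.075),
    source = "fitted")
  specs$radius_distal_breadth_mm <- stature_model(
    "radius", "distal_breadth", "logistic3", c(a = 210, b = 10, c = 0.12),
    source = "fitted")
  specs[measurement_columns()]
}

default_age_weights <- function() {
  counts <- c(241, 94, 49, 37, 35, 27, 11, 19, 11, 19, 8,
              22, 23, 25, 26, 52, 61, 56, 67, 66, 41)
  counts / sum(counts)
}

default_growth_anchors <- function() {
  tibble(age = c(0, 1, 2, 5, 10, 14, 18, 20),
         stature_cm = c(50, 75, 87, 110, 138, 160, 170, 171))
}

#' Simulation configuration for synthetic cohorts
#'
#' @param age_weights 21 non-negative weights for integer ages 0-20
#'   (normalised to sum to 1). The default mirrors the birth-heavy age
#'   distribution of the reference sample (24.3% at age 0).
#' @param growth_anchors Tibble of `(age, stature_cm)` anchors, strictly
#'   increasing in both coordinates; the growth curve interpolates them
#'   piecewise-linearly.
#' @param stature_noise_sd Function of age giving the SD (cm) of additive
#'   Gaussian stature noise; default `2 + 0.25 * age` (heteroscedastic,
#'   wider in adolescence).
#' @param measurement_specs Named list of generative models per measurement
#'   column; default [generative_measurement_specs()].
#' @param measurement_noise_frac Relative SD of multiplicative Gaussian
#'   noise on measurements; default 0.02.
#' @param sex_prob_male Probability an individual is male (sex is recorded
#'   but, matching the pooled-sex design, never used in generation).
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(age_weights = default_age_weights(),
                              growth_anchors = default_growth_anchors(),
                              stature_noise_sd = function(age) 2 + 0.25 * age,
                              measurement_specs = generative_measurement_specs(),
                              measurement_noise_frac = 0.02,
                              sex_prob_male = 0.595) {
  if (length(age_weights) != 21 || any(age_weights < 0) || sum(age_weights) <= 0) {
    abort("age_weights must be 21 non-negative values (ages 0-20) with positive sum.")
  }
  age_weights <- age_weights / sum(age_weights)
  stopifnot(is.data.frame(growth_anchors),
            all(c("age", "stature_cm") %in% names(growth_anchors)))
  if (any(diff(growth_anchors$age) <= 0) || any(diff(growth_anchors$stature_cm) <= 0)) {
    abort("growth_anchors must be strictly increasing in age and stature.")
  }
  if (!is.function(stature_noise_sd)) abort("stature_noise_sd must be a function of age.")
  if (measurement_noise_frac < 0) abort("measurement_noise_frac must be >= 0.")
  structure(
    list(age_weights = age_weights, growth_anchors = growth_anchors,
         stature_noise_sd = stature_noise_sd,
         measurement_specs = measurement_specs,
         measurement_noise_frac = measurement_noise_frac,
         sex_prob_male = sex_prob_male),
    class = "simulation_config"
  )
}

#' Median stature at a given age
#'
#' Monotone piecewise-linear interpolation through the growth anchors —
#' steep in infancy, flattening through adolescence.
#'
#' @param age Age(s) in years, within \[0, 20\].
#' @param anchors Anchor tibble (see [simulation_config()]).
#' @return Median stature in cm.
#' @examples
#' growth_reference(3) # between the age-2 and age-5 anchors
#' @export
growth_reference <- function(age, anchors = default_growth_anchors()) {
  if (any(age < min(anchors$age) | age > max(anchors$age))) {
    abort(sprintf("age must be within [%g, %g].", min(anchors$age), max(anchors$age)))
  }
  approx(anchors$age, anchors$stature_cm, xout = age, method = "linear")$y
}

# clamp simulated statures into a generative curve's attainable range,
# keeping a 2%-of-span margin off the open endpoints
clamp_into_range <- function(y, model) {
  rng <- model_y_range(model)
  if (!all(is.finite(rng))) return(y)
  margin <- 0.02 * diff(rng)
  pmin(pmax(y, rng[1] + margin), rng[2] - margin)
}

#' Simulate a synthetic cohort
#'
#' Each individual draws an integer age from the configured age
#' distribution, a stature from the growth curve plus additive Gaussian
#' noise (truncated above 45 cm), and a sex label; every measurement is then
#' the inverse of its generative curve at that stature (clamped into the
#' curve's attainable range) times multiplicative Gaussian noise. Composite
#' limb lengths are generated from their own curves, like any other
#' measurement. The same seed yields an identical cohort.
#'
#' @param n Number of individuals.
#' @param seed Integer seed (required).
#' @param config A [simulation_config()].
#' @return A cohort tibble: `id`, `sex`, `age_years`, `stature_cm` and the
#'   20 canonical measurement columns (mm).
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' dplyr::glimpse(cohort[, 1:6])
#' @export
simulate_cohort <- function(n, seed, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is required.")
  if (n < 0) abort("n must be non-negative.")
  withr::with_seed(seed, {
    age <- sample(0:20, n, replace = TRUE, prob = config$age_weights)
    stature <- growth_reference(age, config$growth_anchors) +
      rnorm(n, 0, config$stature_noise_sd(age))
    # truncate: redraw the rare statures at or below 45 cm
    for (tries in seq_len(100)) {
      low <- which(stature <= 45)
      if (length(low) == 0) break
      stature[low] <- growth_reference(age[low], config$growth_anchors) +
        rnorm(length(low), 0, config$stature_noise_sd(age[low]))
    }
    stature[stature <= 45] <- 45.1
    sex <- ifelse(runif(n) < config$sex_prob_male, "M", "F")
    out <- tibble(
      id = sprintf("sim-%05d", seq_len(n)),
      sex = sex, age_years = age, stature_cm = stature
    )
    for (col in names(config$measurement_specs)) {
      spec <- config$measurement_specs[[col]]
      x <- invert_model(spec, clamp_into_range(stature, spec))
      out[[col]] <- x * (1 + rnorm(n, 0, config$measurement_noise_frac))
    }
    out
  })
}

#' Simulate (measurement, stature) pairs from one model
#'
#' Unit-level generator for fitting and interval tests: x uniform on
#' `x_range`, `y = f(x) + Gaussian(0, noise_sd_cm)`.
#'
#' @param spec A [stature_model()] (the generative truth).
#' @param n Number of pairs.
#' @param x_range Length-2 range of x (mm), within the model's domain.
#' @param noise_sd_cm Gaussian noise SD on stature (>= 0).
#' @param seed Integer seed (required).
#' @return `tibble(x, y)`.
#' @examples
#' m <- stature_model("humerus", "length", "asymptotic_exponential",
#'                    c(a = 337, b = 329, c = 0.00214))
#' simulate_xy(m, 5, c(50, 350), noise_sd_cm = 4.6, seed = 1)
#' @export
simulate_xy <- function(spec, n, x_range, noise_sd_cm, seed) {
  stopifnot(inherits(spec, "stature_model"))
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is required.")
  if (noise_sd_cm < 0) abort("noise_sd_cm must be >= 0.")
  if (length(x_range) != 2 || x_range[1] <= 0 || diff(x_range) < 0) {
    abort("x_range must be an increasing positive pair (mm).")
  }
  if (n == 0) return(tibble(x = numeric(), y = numeric()))
  withr::with_seed(seed, {
    x <- runif(n, x_range[1], x_range[2])
    y <- evaluate_model(spec, x) + rnorm(n, 0, noise_sd_cm)
    tibble(x = x, y = y)
  })
}
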