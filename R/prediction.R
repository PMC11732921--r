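# Point estimates and prediction intervals (PIs) for new individuals.
#
# A PI bounds a NEW individual's stature, so its variance includes the
# residual noise on top of estimation uncertainty:
#   linear (exact t):    yhat +/- t_{n-2} * s * sqrt(1 + 1/n + (x0-xbar)^2/Sxx)
#   nonlinear (delta t): yhat +/- t_{n-p} * s * sqrt(1 + g(x0)' (J'J)^-1 g(x0))
# Registry models print only s, so their intervals use the conservative
# normal approximation yhat +/- z * s and carry an "approximate" warning.

pi_tbl <- function(model, x0, point, lower, upper, level, method, warnings) {
  tibble(
    bone = model$bone, measurement = model$measurement, family = model$family,
    x_mm = x0, point_cm = point, pi_lower_cm = lower, pi_upper_cm = upper,
    level = level, method = method, warnings = warnings
  )
}

# per-element warning lists: extrapolation plus any model-level warnings
pi_warnings <- function(model, x0, extra = character()) {
  base <- extra
  if (model$sanity_flag) {
    base <- c(base, "model is sanity-flagged: printed coefficients give implausible statures")
  }
  out <- rep(list(base), length(x0))
  if (!is.null(model$x_range)) {
    outside <- x0 < 0.9 * model$x_range[1] | x0 > 1.1 * model$x_range[2]
    for (i in which(outside)) {
      out[[i]] <- c(out[[i]], sprintf(
        "x = %g mm is outside the training range [%g, %g] mm: extrapolation",
        x0[i], model$x_range[1], model$x_range[2]))
    }
  }
  out
}

#' Prediction interval for stature at a measurement value
#'
#' Computes the point estimate and a level-`level` prediction interval for a
#' new individual's stature. Fitted linear models use the exact t interval;
#' fitted nonlinear models use the first-order delta method with a t
#' quantile; `method = "bootstrap"` resamples residuals instead (fitted
#' models only). Registry models, which carry only the printed residual SD,
#' fall back to the normal approximation `point +/- z * s` (method
#' `"approx_z"`) with a warning; a model with no usable residual SD or
#' covariance yields `method = "unavailable"` and a point estimate only.
#' Measurements outside the training range attach an extrapolation warning
#' but are never refused.
#'
#' @param model A [stature_model()] or `stature_fit`.
#' @param x0 Measurement value(s) in millimetres.
#' @param level Coverage level, in (0.5, 0.999). Default 0.95.
#' @param method `"auto"` (exact t / delta t / approx z as available) or
#'   `"bootstrap"` (residual bootstrap, percentile interval).
#' @param B Bootstrap replicates (when `method = "bootstrap"`).
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with one row per `x0`: model identity, `x_mm`,
#'   `point_cm`, `pi_lower_cm`, `pi_upper_cm`, `level`, `method`, and a
#'   `warnings` list-column.
#' @examples
#' fit <- fit_linear(c(100, 200, 300, 400), c(75, 115, 160, 175))
#' prediction_interval(fit, 250)
#' @export
prediction_interval <- function(model, x0, level = 0.95,
                                method = c("auto", "bootstrap"),
                                B = 999, seed = NULL) {
  method <- match.arg(method)
  fit <- NULL
  if (inherits(model, "stature_fit")) {
    fit <- model
    model <- fit$model
  }
  if (!inherits(model, "stature_model")) abort("`model` must be a stature_model or stature_fit.")
  if (!isTRUE(model$converged)) abort("Model did not converge; no prediction possible.")
  if (level <= 0.5 || level >= 0.999) abort("level must be in (0.5, 0.999).")
  check_x(x0)
  if (method == "bootstrap") {
    if (is.null(fit) || is.null(fit$data)) {
      abort("Bootstrap intervals need a stature_fit with training data.")
    }
    return(bootstrap_interval(fit, x0, level = level, B = B, seed = seed))
  }
  alpha2 <- (1 - level) / 2
  point <- evaluate_model(model, x0)
  s <- model$residual_sd
  if (model$source == "fitted" && !is.na(model$n)) {
    if (model$family == "linear") {
      se <- s * sqrt(1 + 1 / model$n + (x0 - model$x_mean)^2 / model$sxx)
      half <- qt(1 - alpha2, df = model$n - 2) * se
      return(pi_tbl(model, x0, point, point - half, point + half, level,
                    "exact_t", pi_warnings(model, x0)))
    }
    if (is.null(model$cov_unscaled)) {
      return(pi_tbl(model, x0, point, NA_real_, NA_real_, level, "unavailable",
                    pi_warnings(model, x0, "parameter covariance unavailable: no interval")))
    }
    G <- model_gradient(model, x0)
    quad <- rowSums((G %*% model$cov_unscaled) * G)
    half <- qt(1 - alpha2, df = model$n - 3) * s * sqrt(1 + quad)
    return(pi_tbl(model, x0, point, point - half, point + half, level,
                  "delta_t", pi_warnings(model, x0)))
  }
  # registry model: only the printed residual SD is available
  if (is.finite(s)) {
    half <- qnorm(1 - alpha2) * s
    return(pi_tbl(model, x0, point, point - half, point + half, level, "approx_z",
                  pi_warnings(model, x0, "approximate interval (z * printed residual SD); refit for an exact PI")))
  }
  pi_tbl(model, x0, point, NA_real_, NA_real_, level, "unavailable",
         pi_warnings(model, x0, "no residual SD available: point estimate only"))
}

# residual bootstrap: refit on y* = fitted + resampled residuals, predict at
# x0, add a freshly resampled residual; percentile interval
bootstrap_interval <- function(fit, x0, level = 0.95, B = 999, seed = NULL) {
  model <- fit$model
  x <- fit$data$x
  fitted_y <- evaluate_model(model, x)
  resid <- fit$data$y - fitted_y
  draw <- function() {
    yb <- fitted_y + sample(resid, length(resid), replace = TRUE)
    refit <- tryCatch(
      if (model$family == "linear") {
        fit_linear(x, yb, bone = model$bone, measurement = model$measurement)
      } else {
        fit_nonlinear(model$family, x, yb, bone = model$bone,
                      measurement = model$measurement)
      },
      error = function(e) NULL
    )
    if (is.null(refit) || !refit$converged) return(rep(NA_real_, length(x0)))
    evaluate_model(refit$model, x0) + sample(resid, length(x0), replace = TRUE)
  }
  sim <- withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    vapply(seq_len(B), function(b) draw(), numeric(length(x0)))
  })
  sim <- matrix(sim, nrow = length(x0))
  alpha2 <- (1 - level) / 2
  point <- evaluate_model(model, x0)
  lower <- apply(sim, 1, quantile, probs = alpha2, na.rm = TRUE, names = FALSE)
  upper <- apply(sim, 1, quantile, probs = 1 - alpha2, na.rm = TRUE, names = FALSE)
  pi_tbl(model, x0, point, lower, upper, level, "bootstrap", pi_warnings(model, x0))
}

# pick models per family preference, one or two per measurement
select_models <- function(models, families) {
  usable <- models[!map_lgl(models$model, is.null), , drop = FALSE]
  if ("converged" %in% names(usable)) usable <- usable[usable$converged, , drop = FALSE]
  if (families %in% c("both", "linear", "nonlinear")) {
    keep <- switch(families,
      both = rep(TRUE, nrow(usable)),
      linear = usable$family == "linear",
      nonlinear = usable$family != "linear"
    )
    return(usable[keep, , drop = FALSE])
  }
  prefer_nonlinear <- families == "nonlinear_first"
  usable$is_nonlinear <- usable$family != "linear"
  usable <- usable %>%
    group_by(.data$bone, .data$measurement) %>%
    filter(.data$is_nonlinear == if (prefer_nonlinear) max(.data$is_nonlinear) else min(.data$is_nonlinear)) %>%
    ungroup()
  usable$is_nonlinear <- NULL
  usable
}

#' Estimate stature for individuals from their measurements
#'
#' The main user entry point: derives the composite limb lengths, then for
#' every available measurement of every individual computes a stature point
#' estimate and prediction interval from each selected model. Results are
#' ordered (within individual) by the source model's published mean absolute
#' deviation — most precise first — falling back to the fitted residual SD
#' for refitted model sets. Sanity-flagged models contribute results tagged
#' with a warning.
#'
#' @param data Cohort tibble with canonical measurement columns (one row per
#'   individual); see [read_cohort()].
#' @param models A model table: [load_registry()] (default) or the output of
#'   [fit_stature_models()].
#' @param level Prediction-interval level.
#' @param families `"both"` (default: every available model),
#'   `"linear"`/`"nonlinear"` (one family only), or
#'   `"nonlinear_first"`/`"linear_first"` (one result per measurement,
#'   preferring that family).
#' @return A tibble with one row per (individual, measurement, model):
#'   `id`, model identity, `x_mm`, `point_cm`, `pi_lower_cm`, `pi_upper_cm`,
#'   `level`, `method`, `precision_cm` (ordering key) and a `warnings`
#'   list-column. Empty (with a message) when no measurement matches an
#'   available model.
#' @examples
#' case <- tibble::tibble(id = "case-1", humerus_length_mm = 300)
#' estimate_stature(case)
#' @export
estimate_stature <- function(data, models = load_registry(), level = 0.95,
                             families = c("both", "nonlinear_first",
                                          "linear_first", "linear", "nonlinear")) {
  families <- match.arg(families)
  stopifnot(is.data.frame(data))
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data <- add_composite_lengths(data)
  chosen <- select_models(models, families)
  # ordering key: printed MAD where available, else fitted residual SD
  chosen$precision_cm <- if ("mad_cm" %in% names(chosen)) {
    chosen$mad_cm
  } else {
    chosen$residual_sd_cm
  }
  rows <- list()
  for (j in seq_len(nrow(chosen))) {
    col <- paste0(chosen$bone[j], "_", chosen$measurement[j], "_mm")
    if (!col %in% names(data)) next
    present <- which(!is.na(data[[col]]))
    if (length(present) == 0) next
    res <- prediction_interval(chosen$model[[j]], data[[col]][present], level = level)
    res$id <- as.character(data$id[present])
    res$precision_cm <- chosen$precision_cm[j]
    rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) {
    inform("No measurement in the input matches an available model; nothing to estimate.")
    return(tibble(
      id = character(), bone = character(), measurement = character(),
      family = character(), x_mm = numeric(), point_cm = numeric(),
      pi_lower_cm = numeric(), pi_upper_cm = numeric(), level = numeric(),
      method = character(), precision_cm = numeric(), warnings = list()
    ))
  }
  out <- list_rbind(rows)
  out <- out[order(out$id, out$precision_cm, out$bone, out$measurement, out$family), ]
  out[, c("id", "bone", "measurement", "family", "x_mm", "point_cm",
          "pi_lower_cm", "pi_upper_cm", "level", "method", "precision_cm",
          "warnings")]
}
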