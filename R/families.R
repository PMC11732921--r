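# The three regression families relating a long-bone measurement x (mm) to
# stature y (cm):
#   linear                  y = a*x + b
#   asymptotic_exponential  y = a - b*exp(-c*x)   (lengths; saturating)
#   logistic3               y = a / (1 + b*exp(-c*x))   (breadths; sigmoid)

model_families <- function() c("linear", "asymptotic_exponential", "logistic3")

n_params <- function(family) if (family == "linear") 2L else 3L

# exp with the exponent clamped so overflow never produces NaN/Inf surprises;
# underflow goes to 0 naturally
safe_exp <- function(t) exp(pmin(t, 700))

#' Construct a stature regression model
#'
#' A `stature_model` couples a functional family with named coefficients and
#' (for fitted models) the training summaries needed for prediction
#' intervals. Coefficients follow the field's convention: `a` and `b` for the
#' linear family (slope and intercept), `a`, `b`, `c` for the nonlinear
#' families. Input `x` is always a measurement in millimetres; output is
#' stature in centimetres.
#'
#' @param bone,measurement Bone and measurement-type names from
#'   [measurement_dictionary()].
#' @param family One of `"linear"`, `"asymptotic_exponential"`, `"logistic3"`.
#' @param coefficients Named numeric vector (`a`, `b` and, for nonlinear
#'   families, `c`). All must be finite. For the nonlinear families `a <= 0`
#'   or `c <= 0` is flagged (not rejected) via `sanity_flag`.
#' @param n,residual_sd,x_mean,sxx,cov_unscaled,x_range,converged Optional
#'   fitted-model fields: training size, residual standard deviation (cm),
#'   training mean of x (mm), centred sum of squares of x (linear only), the
#'   unscaled parameter covariance \eqn{(J^T J)^{-1}} (nonlinear only),
#'   training x range, and convergence status.
#' @param sanity_flag Logical; marks models whose printed coefficients yield
#'   implausible statures at typical adult measurements.
#' @param source `"registry"` or `"fitted"`.
#' @return An object of class `stature_model`.
#' @examples
#' m <- stature_model("humerus", "length", "linear", c(a = 0.46, b = 25.3))
#' evaluate_model(m, 300)
#' @export
stature_model <- function(bone, measurement, family,
                          coefficients,
                          n = NA_integer_, residual_sd = NA_real_,
                          x_mean = NA_real_, sxx = NA_real_,
                          cov_unscaled = NULL, x_range = NULL,
                          converged = TRUE, sanity_flag = FALSE,
                          source = "fitted") {
  family <- match.arg(family, model_families())
  if (!is.na(bone)) {
    dict <- measurement_dictionary()
    if (!any(dict$bone == bone & dict$measurement == measurement)) {
      abort(sprintf("(%s, %s) is not a valid bone/measurement combination.", bone, measurement))
    }
  }
  coefficients <- unlist(coefficients)
  need <- if (family == "linear") c("a", "b") else c("a", "b", "c")
  if (!all(need %in% names(coefficients))) {
    abort(sprintf("family %s needs coefficients %s", family, paste(need, collapse = ", ")))
  }
  coefficients <- coefficients[need]
  if (!all(is.finite(coefficients))) abort("All coefficients must be finite.")
  if (family != "linear" && (coefficients[["a"]] <= 0 || coefficients[["c"]] <= 0)) {
    sanity_flag <- TRUE
  }
  structure(
    list(
      bone = bone, measurement = measurement, family = family,
      coefficients = coefficients,
      n = n, residual_sd = residual_sd, x_mean = x_mean, sxx = sxx,
      cov_unscaled = cov_unscaled, x_range = x_range,
      converged = converged, sanity_flag = sanity_flag, source = source
    ),
    class = "stature_model"
  )
}

#' @export
print.stature_model <- function(x, ...) {
  co <- paste(sprintf("%s = %g", names(x$coefficients), x$coefficients), collapse = ", ")
  cat(sprintf("<stature_model> %s %s [%s]\n", x$bone, x$measurement, x$family))
  cat("  ", co, "\n", sep = "")
  if (!is.na(x$residual_sd)) {
    cat(sprintf("  residual sd %.3g cm%s\n", x$residual_sd,
                if (!is.na(x$n)) sprintf(", n = %d", x$n) else ""))
  }
  if (!x$converged) cat("  NOT CONVERGED - unusable for prediction\n")
  if (x$sanity_flag) cat("  sanity-flagged: predictions may be implausible\n")
  invisible(x)
}

model_id <- function(model) {
  paste(model$bone, model$measurement, model$family, sep = ":")
}

check_x <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("Measurement x must be finite and > 0 (millimetres).")
  }
  invisible(x)
}

# family mean function and its parameter gradient on a bare coefficient
# vector (used in fitting, where no stature_model object exists yet)
family_eval <- function(family, co, x) {
  switch(family,
    linear = co[["a"]] * x + co[["b"]],
    asymptotic_exponential = co[["a"]] - co[["b"]] * safe_exp(-co[["c"]] * x),
    logistic3 = co[["a"]] / (1 + co[["b"]] * safe_exp(-co[["c"]] * x))
  )
}

family_grad <- function(family, co, x) {
  switch(family,
    linear = cbind(a = x, b = rep(1, length(x))),
    asymptotic_exponential = {
      e <- safe_exp(-co[["c"]] * x)
      cbind(a = rep(1, length(x)), b = -e, c = co[["b"]] * x * e)
    },
    logistic3 = {
      e <- safe_exp(-co[["c"]] * x)
      D <- 1 + co[["b"]] * e
      cbind(a = 1 / D, b = -co[["a"]] * e / D^2, c = co[["a"]] * co[["b"]] * x * e / D^2)
    }
  )
}

#' Evaluate a stature model at measurement values
#'
#' @param model A [stature_model()].
#' @param x Measurement values in millimetres (finite, > 0).
#' @return Predicted stature in centimetres, one value per element of `x`.
#' @examples
#' m <- stature_model("humerus", "length", "linear", c(a = 0.46, b = 25.3))
#' evaluate_model(m, 300) # 163.3
#' @export
evaluate_model <- function(model, x) {
  check_x(x)
  family_eval(model$family, model$coefficients, x)
}

#' Gradient of a stature model with respect to its parameters
#'
#' Analytic partial derivatives of the mean function, used for delta-method
#' prediction intervals and as the Jacobian in nonlinear fitting.
#'
#' @inheritParams evaluate_model
#' @return A `length(x)` by `p` matrix with one column per coefficient.
#' @export
model_gradient <- function(model, x) {
  check_x(x)
  family_grad(model$family, model$coefficients, x)
}

# attainable stature interval (open) for a model, for x in (0, Inf)
model_y_range <- function(model) {
  co <- model$coefficients
  switch(model$family,
    linear = c(-Inf, Inf),
    asymptotic_exponential = sort(c(co[["a"]] - co[["b"]], co[["a"]])),
    logistic3 = c(co[["a"]] / (1 + co[["b"]]), co[["a"]])
  )
}

#' Invert a stature model: measurement for a given stature
#'
#' Closed-form inverse of the mean function. Round trips with
#' [evaluate_model()] to relative tolerance 1e-10. Used by the synthetic
#' cohort generator to derive measurements from simulated statures.
#'
#' @param model A [stature_model()].
#' @param y Stature in centimetres, strictly inside the family's attainable
#'   range: any value for linear; `(a - b, a)` for the asymptotic
#'   exponential; `(a / (1 + b), a)` for the three-parameter logistic.
#' @return Measurement in millimetres.
#' @examples
#' m <- stature_model("femur", "midshaft_breadth", "logistic3",
#'                    c(a = 209, b = 10.8, c = 0.153))
#' invert_model(m, 104.5) # logistic midpoint: log(10.8) / 0.153
#' @export
invert_model <- function(model, y) {
  if (!is.numeric(y) || any(!is.finite(y))) abort("Stature y must be finite.")
  co <- model$coefficients
  rng <- model_y_range(model)
  if (model$family != "linear" && any(y <= rng[1] | y >= rng[2])) {
    abort(sprintf(
      "Stature %s cm is outside the attainable range (%.6g, %.6g) cm of the %s model.",
      paste(format(y[y <= rng[1] | y >= rng[2]]), collapse = ", "),
      rng[1], rng[2], model$family
    ))
  }
  switch(model$family,
    linear = (y - co[["b"]]) / co[["a"]],
    asymptotic_exponential = -log((co[["a"]] - y) / co[["b"]]) / co[["c"]],
    logistic3 = -log((co[["a"]] / y - 1) / co[["b"]]) / co[["c"]]
  )
}
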