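# Fitting the three families to (measurement, stature) training pairs.
# Linear models are ordinary least squares via stats::lm; nonlinear models
# are Levenberg-Marquardt least squares (minpack.lm::nls.lm) with the
# analytic Jacobian from family_grad and linearisation-based starting values.

new_stature_fit <- function(model, iterations, objective, converged, message,
                            coef_table, objective_trace = numeric(),
                            eval_trace = numeric(), data = NULL) {
  structure(
    list(model = model, iterations = iterations, objective = objective,
         converged = converged, message = message, coef_table = coef_table,
         objective_trace = objective_trace, eval_trace = eval_trace,
         data = data),
    class = "stature_fit"
  )
}

#' @export
print.stature_fit <- function(x, ...) {
  cat(sprintf("<stature_fit> %s | converged: %s | SSE %.4g | iterations %d\n",
              x$model$family, x$converged, x$objective, x$iterations))
  print(x$model)
  invisible(x)
}

#' Fit a linear stature model by ordinary least squares
#'
#' Regresses stature (cm) on a single measurement (mm): `y = a x + b`. The
#' fit stores the training summaries (`n`, residual SD, mean of x, centred
#' sum of squares of x) that the exact t prediction interval needs.
#'
#' @param x Measurements in millimetres (at least 3, not all equal).
#' @param y Known statures in centimetres, same length as `x`.
#' @param bone,measurement Optional labels identifying what was measured.
#' @return A `stature_fit`: the fitted [stature_model()] plus the objective
#'   (sum of squared residuals, cm^2), a per-coefficient Wald table, and a
#'   convergence status (always `TRUE` for OLS).
#' @examples
#' fit_linear(c(100, 200, 300), c(70, 120, 160))
#' @export
fit_linear <- function(x, y, bone = NA_character_, measurement = NA_character_) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Linear fit needs at least 3 complete pairs.")
  if (diff(range(x)) == 0) abort("Degenerate design: x is constant.")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  sse <- sum(fit$residuals^2)
  s <- sqrt(sse / (n - 2))
  sm <- suppressWarnings(summary(fit))$coefficients  # silence perfect-fit note
  coef_table <- tibble(
    term = c("a", "b"),
    estimate = c(slope, intercept),
    std_error = c(sm["x", 2], sm["(Intercept)", 2]),
    statistic = c(sm["x", 3], sm["(Intercept)", 3]),
    p_value = c(sm["x", 4], sm["(Intercept)", 4])
  )
  model <- stature_model(
    bone, measurement, "linear", c(a = slope, b = intercept),
    n = n, residual_sd = s, x_mean = mean(x), sxx = sum((x - mean(x))^2),
    x_range = range(x), converged = TRUE, source = "fitted"
  )
  new_stature_fit(model, iterations = 1L, objective = sse, converged = TRUE,
                  message = "ordinary least squares", coef_table = coef_table,
                  data = tibble(x = x, y = y))
}

# linearisation-based starting values (log transform for the asymptotic
# exponential, logit transform for the logistic); both put the optimizer in
# a basin that converges for well-formed growth data
nls_start <- function(family, x, y) {
  a0 <- 1.05 * max(y)
  if (family == "asymptotic_exponential") {
    z <- log(pmax(a0 - y, 1e-8))
    lf <- lm(z ~ x)
    b0 <- exp(unname(coef(lf)[1]))
    c0 <- max(-unname(coef(lf)[2]), 1e-6)
  } else {
    p <- pmin(pmax(y / a0, 1e-6), 1 - 1e-6)
    z <- log(p / (1 - p))
    lf <- lm(z ~ x)
    b0 <- max(exp(-unname(coef(lf)[1])), 1e-8)
    c0 <- max(unname(coef(lf)[2]), 1e-6)
  }
  c(a = a0, b = b0, c = c0)
}

#' Fit a nonlinear stature model by Levenberg-Marquardt least squares
#'
#' Minimises the sum of squared residuals for the asymptotic exponential
#' (`y = a - b exp(-c x)`, lengths) or three-parameter logistic
#' (`y = a / (1 + b exp(-c x))`, breadths) with the analytic Jacobian.
#' Non-convergence within `max_iter` is reported (`converged = FALSE`),
#' never raised as an error; the returned model is then unusable for
#' prediction.
#'
#' @inheritParams fit_linear
#' @param family `"asymptotic_exponential"` or `"logistic3"`.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Relative convergence tolerance on the objective, parameters
#'   and gradient.
#' @return A `stature_fit`. The fitted model carries `residual_sd =
#'   sqrt(SSE / (n - 3))` and the unscaled covariance \eqn{(J^T J)^{-1}}
#'   used by delta-method prediction intervals; if \eqn{J^T J} is singular
#'   the covariance is marked unavailable and intervals are disabled.
#' @examples
#' x <- seq(50, 350, by = 25)
#' y <- 337 - 329 * exp(-0.00214 * x)
#' fit_nonlinear("asymptotic_exponential", x, y)
#' @export
fit_nonlinear <- function(family, x, y,
                          bone = NA_character_, measurement = NA_character_,
                          max_iter = 200, tol = 1e-8) {
  family <- match.arg(family, c("asymptotic_exponential", "logistic3"))
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) abort("Nonlinear fit needs at least 5 complete pairs.")
  if (diff(range(y)) == 0) abort("Non-identifiable: y has no spread.")
  start <- nls_start(family, x, y)
  evals <- new.env(parent = emptyenv())
  evals$sse <- numeric()
  res <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) {
      r <- y - family_eval(family, par, x)
      evals$sse <- c(evals$sse, sum(r^2))
      r
    },
    jac = function(par) -family_grad(family, par, x),
    control = minpack.lm::nls.lm.control(
      maxiter = min(max_iter, 1024), ftol = tol, ptol = tol, gtol = tol
    )
  )
  par <- setNames(coef(res), c("a", "b", "c"))
  sse <- res$deviance
  s <- sqrt(sse / (n - 3))
  converged <- res$info %in% 1:4
  # covariance from the analytic Jacobian at the solution
  J <- family_grad(family, par, x)
  jtj <- crossprod(J)
  cov_unscaled <- tryCatch(solve(jtj), error = function(e) NULL)
  message <- res$message
  if (converged && is.null(cov_unscaled)) {
    message <- paste(message, "| J'J singular: covariance unavailable, prediction intervals disabled")
  }
  se <- if (!is.null(cov_unscaled)) s * sqrt(pmax(diag(cov_unscaled), 0)) else rep(NA_real_, 3)
  coef_table <- tibble(
    term = names(par), estimate = unname(par), std_error = unname(se),
    statistic = unname(par) / unname(se),
    p_value = 2 * stats::pt(abs(unname(par) / unname(se)), df = n - 3, lower.tail = FALSE)
  )
  model <- stature_model(
    bone, measurement, family, par,
    n = n, residual_sd = s, x_mean = mean(x),
    cov_unscaled = cov_unscaled, x_range = range(x),
    converged = converged, source = "fitted"
  )
  # accepted-step objective trace: Levenberg-Marquardt only moves on
  # improvement, so the accepted iterates are the running-minimum
  # subsequence of all trial evaluations
  accepted <- evals$sse[evals$sse <= cummin(evals$sse)]
  new_stature_fit(model, iterations = res$niter, objective = sse,
                  converged = converged, message = message,
                  coef_table = coef_table,
                  objective_trace = accepted, eval_trace = evals$sse,
                  data = tibble(x = x, y = y))
}

# which nonlinear family a measurement gets: saturating curve for lengths,
# sigmoid for breadths
nonlinear_family_for <- function(measurement) {
  ifelse(measurement == "length", "asymptotic_exponential", "logistic3")
}

#' Fit the full model grid to a training cohort
#'
#' Attempts all 40 models — for each of the 20 measurements (composite limb
#' lengths are derived first) a linear fit plus the measurement's nonlinear
#' family (asymptotic exponential for lengths, three-parameter logistic for
#' breadths). Pairs with a missing measurement are dropped per model
#' (complete-case); a measurement with fewer than `min_pairs` complete pairs
#' is skipped with a warning. Fit failures and non-convergence are recorded
#' in the returned table, never raised.
#'
#' @param training Cohort tibble with known `stature_cm` (see
#'   [read_cohort()], [simulate_cohort()]).
#' @param min_pairs Minimum complete pairs required to attempt a
#'   measurement's models.
#' @param max_iter,tol Passed to [fit_nonlinear()].
#' @return A tibble with one row per attempted model: `bone`, `measurement`,
#'   `family`, `n`, `converged`, `residual_sd_cm`, `objective`,
#'   `iterations`, `message`, and list-columns `fit` (`stature_fit`) and
#'   `model` ([stature_model()]); usable directly as the `models` argument
#'   of [estimate_stature()] and [evaluate_models()].
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 1)
#' fits <- fit_stature_models(cohort)
#' table(fits$family, fits$converged)
#' @export
fit_stature_models <- function(training, min_pairs = 20, max_iter = 200, tol = 1e-8) {
  stopifnot(is.data.frame(training))
  if (!"stature_cm" %in% names(training)) {
    abort("Training data must carry known stature (`stature_cm`).")
  }
  training <- add_composite_lengths(training)
  dict <- measurement_dictionary()
  rows <- list()
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    xy <- if (col %in% names(training)) {
      tibble(x = training[[col]], y = training$stature_cm)
    } else {
      tibble(x = numeric(), y = numeric())
    }
    xy <- xy[complete.cases(xy), ]
    if (nrow(xy) < min_pairs) {
      warn(sprintf("Skipping %s: only %d complete pairs (< %d).", col, nrow(xy), min_pairs))
      next
    }
    for (family in c("linear", nonlinear_family_for(dict$measurement[i]))) {
      fit <- tryCatch(
        {
          if (family == "linear") {
            fit_linear(xy$x, xy$y, bone = dict$bone[i], measurement = dict$measurement[i])
          } else {
            fit_nonlinear(family, xy$x, xy$y, bone = dict$bone[i],
                          measurement = dict$measurement[i],
                          max_iter = max_iter, tol = tol)
          }
        },
        error = function(e) e
      )
      rows[[length(rows) + 1]] <- if (inherits(fit, "error")) {
        tibble(
          bone = dict$bone[i], measurement = dict$measurement[i], family = family,
          n = nrow(xy), converged = FALSE, residual_sd_cm = NA_real_,
          objective = NA_real_, iterations = 0L,
          message = conditionMessage(fit), fit = list(NULL), model = list(NULL)
        )
      } else {
        fitted_model <- fit$model
        tibble(
          bone = dict$bone[i], measurement = dict$measurement[i], family = family,
          n = fitted_model$n, converged = fit$converged,
          residual_sd_cm = fitted_model$residual_sd, objective = fit$objective,
          iterations = fit$iterations, message = fit$message,
          fit = list(fit), model = list(fitted_model)
        )
      }
    }
  }
  list_rbind(rows)
}

#' @exportS3Method generics::tidy
tidy.stature_fit <- function(x, ...) x$coef_table

#' @exportS3Method generics::glance
glance.stature_fit <- function(x, ...) {
  tibble(
    family = x$model$family, n = x$model$n,
    residual_sd_cm = x$model$residual_sd, objective = x$objective,
    iterations = x$iterations, converged = x$converged
  )
}
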