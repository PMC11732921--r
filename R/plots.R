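# Convenience ggplot2 output: fitted curves, interval forests, Bland-Altman.

#' @exportS3Method ggplot2::autoplot
autoplot.stature_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$y <- evaluate_model(object$model, grid$x)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_line(data = grid, colour = "#2166ac", linewidth = 0.9) +
    labs(
      x = sprintf("%s %s (mm)", object$model$bone, object$model$measurement),
      y = "stature (cm)",
      title = sprintf("%s fit%s", object$model$family,
                      if (!object$converged) " (NOT converged)" else "")
    )
}

#' Forest plot of stature estimates for one individual
#'
#' One interval per (measurement, model), ordered as returned by
#' [estimate_stature()] (most precise first).
#'
#' @param estimates Output of [estimate_stature()], ideally one individual.
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) > 0)
  est <- estimates
  est$label <- sprintf("%s %s (%s)", est$bone, est$measurement,
                       ifelse(est$family == "linear", "linear", "nonlinear"))
  est$label <- factor(est$label, levels = rev(unique(est$label)))
  ggplot(est, aes(x = .data$point_cm, y = .data$label)) +
    geom_pointrange(aes(xmin = .data$pi_lower_cm, xmax = .data$pi_upper_cm)) +
    facet_wrap(~id) +
    labs(x = "stature (cm)", y = NULL,
         title = sprintf("Stature estimates with %d%% prediction intervals",
                         round(100 * est$level[1])))
}

#' Bland-Altman plot of predicted vs known stature
#'
#' Differences against known stature, with the mean difference (solid) and
#' the limits of agreement (dashed).
#'
#' @param predicted,known Equal-length numeric vectors (cm).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(predicted, known) {
  ba <- bland_altman(predicted, known)
  d <- tibble(known = known, diff = predicted - known)
  ggplot(d, aes(x = .data$known, y = .data$diff)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = ba$bias_cm) +
    geom_hline(yintercept = c(ba$lower_limit_cm, ba$upper_limit_cm),
               linetype = "dashed") +
    labs(x = "known stature (cm)", y = "predicted - known (cm)",
         title = "Bland-Altman agreement")
}
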