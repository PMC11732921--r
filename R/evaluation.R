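# Validation battery: train/test split, precision (MAD), distributional fit
# (two-sample Kolmogorov-Smirnov), correlation (Kendall's tau-b), agreement
# (Bland-Altman limits), 95%-PI test accuracy, and the misclassification
# cross-tabulation by measurement and model type.

#' Split a cohort into training and hold-out sets
#'
#' Random, disjoint, exhaustive partition; the training set has
#' `round(n * train_frac)` rows. The same seed always reproduces the same
#' membership.
#'
#' @param data Cohort tibble.
#' @param train_frac Training fraction, in (0, 1). Default 0.8.
#' @param seed Integer seed (required, for reproducibility).
#' @return `list(train = , test = )` of tibbles.
#' @examples
#' split <- train_test_split(simulate_cohort(100, seed = 1), seed = 42)
#' nrow(split$train) # 80
#' @export
train_test_split <- function(data, train_frac = 0.8, seed) {
  stopifnot(is.data.frame(data))
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is required.")
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0, 1).")
  n <- nrow(data)
  if (n < 5) abort("Need at least 5 rows to split.")
  n_train <- round(n * train_frac)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Mean absolute deviation between predicted and known stature
#'
#' @param predicted,known Equal-length numeric vectors (cm).
#' @return Mean of `|predicted - known|`, in cm.
#' @examples
#' mean_absolute_deviation(c(100, 110), c(102, 106)) # 3
#' @export
mean_absolute_deviation <- function(predicted, known) {
  if (length(predicted) != length(known)) abort("predicted and known must have equal length.")
  if (length(predicted) == 0) abort("Empty input.")
  mean(abs(predicted - known))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D is the supremum distance between the two empirical distribution
#' functions; the p-value uses the asymptotic two-sample KS distribution.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return `list(D = , p = )`.
#' @examples
#' ks_two_sample(c(1, 2), c(1.5, 2.5))$D # 0.5
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) abort("Both samples must be non-empty.")
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Kendall's tau-b correlation
#'
#' Tie-corrected Kendall rank correlation between a measurement and stature.
#'
#' @param x,y Equal-length numeric vectors of length >= 2; neither may be
#'   constant (all-tied input leaves tau undefined).
#' @return Tau-b, in \[-1, 1\].
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2)) # 1/3
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 2) abort("Need at least 2 pairs.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Kendall's tau is undefined when either variable is all tied.")
  }
  unname(cor(x, y, method = "kendall"))
}

#' Percent of prediction intervals covering the known stature
#'
#' The test-accuracy metric: the share of held-out individuals whose known
#' stature falls inside the model's prediction interval. Results without an
#' interval (`method = "unavailable"`) are excluded with a warning.
#'
#' @param results Prediction tibble (from [prediction_interval()] or
#'   [estimate_stature()]) with a `known_cm` column appended.
#' @return Percent in \[0, 100\], reported to 0.1.
#' @export
test_accuracy <- function(results) {
  stopifnot(is.data.frame(results))
  need <- c("pi_lower_cm", "pi_upper_cm", "known_cm")
  if (!all(need %in% names(results))) {
    abort("results must carry pi_lower_cm, pi_upper_cm and known_cm.")
  }
  if ("method" %in% names(results) && any(results$method == "unavailable")) {
    warn(sprintf("Excluding %d result(s) without an interval (method = 'unavailable').",
                 sum(results$method == "unavailable")))
    results <- results[results$method != "unavailable", , drop = FALSE]
  }
  if (nrow(results) == 0) abort("No results with intervals to assess.")
  inside <- results$known_cm >= results$pi_lower_cm & results$known_cm <= results$pi_upper_cm
  round(100 * mean(inside), 1)
}

#' Bland-Altman agreement between predicted and known stature
#'
#' Bias is the mean of the differences `predicted - known`; the limits of
#' agreement are `bias +/- 1.96 * sd` (sample SD, n - 1).
#'
#' @param predicted,known Equal-length numeric vectors (cm), n >= 2.
#' @return `tibble(bias_cm, lower_limit_cm, upper_limit_cm)`.
#' @examples
#' bland_altman(c(101, 99), c(100, 100))
#' @export
bland_altman <- function(predicted, known) {
  if (length(predicted) != length(known)) abort("predicted and known must have equal length.")
  if (length(predicted) < 2) abort("Bland-Altman needs at least 2 pairs.")
  d <- predicted - known
  bias <- mean(d)
  spread <- 1.96 * sd(d)
  tibble(bias_cm = bias, lower_limit_cm = bias - spread, upper_limit_cm = bias + spread)
}

# per-model hold-out predictions with the known stature attached
predict_holdout <- function(models, test, level = 0.95) {
  test <- add_composite_lengths(test)
  if (!"stature_cm" %in% names(test)) abort("Test records must carry known stature (`stature_cm`).")
  if (!"id" %in% names(test)) test$id <- as.character(seq_len(nrow(test)))
  usable <- models[!map_lgl(models$model, is.null), , drop = FALSE]
  if ("converged" %in% names(usable)) usable <- usable[usable$converged, , drop = FALSE]
  rows <- list()
  for (j in seq_len(nrow(usable))) {
    col <- paste0(usable$bone[j], "_", usable$measurement[j], "_mm")
    if (!col %in% names(test)) next
    ok <- which(!is.na(test[[col]]) & !is.na(test$stature_cm))
    if (length(ok) == 0) next
    res <- prediction_interval(usable$model[[j]], test[[col]][ok], level = level)
    res$id <- as.character(test$id[ok])
    res$known_cm <- test$stature_cm[ok]
    rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) abort("No model matches any measurement in the test set.")
  list_rbind(rows)
}

#' Validate models against a hold-out sample
#'
#' Mirrors the published per-model validation: for each converged model,
#' complete-case hold-out pairs give Kendall's tau between measurement and
#' known stature, the training residual SD, the two-sample KS comparison of
#' predicted vs known stature, 95%-PI test accuracy, MAD, and Bland-Altman
#' bias and limits of agreement. Point estimates (not interval midpoints)
#' feed KS and MAD. Models with fewer than 5 usable pairs are reported with
#' metrics `NA` and a warning.
#'
#' @param models Model table ([fit_stature_models()] output or
#'   [load_registry()]).
#' @param test Hold-out cohort tibble with known `stature_cm`.
#' @param level Prediction-interval level for the accuracy metric.
#' @param keep_predictions If `TRUE`, the per-prediction table is attached
#'   as the `"predictions"` attribute (used by
#'   [misclassification_report()]).
#' @return A tibble with one row per model: `bone`, `measurement`,
#'   `family`, `n_test`, `kendall_tau`, `residual_sd_cm`, `ks_D`, `ks_p`,
#'   `test_accuracy_pct`, `mad_cm`, `bias_cm`, `lower_limit_cm`,
#'   `upper_limit_cm`.
#' @examples
#' cohort <- simulate_cohort(400, seed = 7)
#' split <- train_test_split(cohort, seed = 7)
#' fits <- fit_stature_models(split$train)
#' evaluate_models(fits, split$test)
#' @export
evaluate_models <- function(models, test, level = 0.95, keep_predictions = FALSE) {
  preds <- predict_holdout(models, test, level = level)
  key <- paste(preds$bone, preds$measurement, preds$family, sep = ":")
  rows <- map(unique(key), function(k) {
    p <- preds[key == k, , drop = FALSE]
    base <- tibble(bone = p$bone[1], measurement = p$measurement[1],
                   family = p$family[1], n_test = nrow(p))
    if (nrow(p) < 5) {
      warn(sprintf("Model %s has only %d usable test pairs; metrics withheld.", k, nrow(p)))
      return(mutate(base,
        kendall_tau = NA_real_, residual_sd_cm = NA_real_, ks_D = NA_real_,
        ks_p = NA_real_, test_accuracy_pct = NA_real_, mad_cm = NA_real_,
        bias_cm = NA_real_, lower_limit_cm = NA_real_, upper_limit_cm = NA_real_))
    }
    ks <- ks_two_sample(p$known_cm, p$point_cm)
    ba <- bland_altman(p$point_cm, p$known_cm)
    mutate(base,
      kendall_tau = kendall_tau(p$x_mm, p$known_cm),
      residual_sd_cm = models$model[[match(k, paste(models$bone, models$measurement, models$family, sep = ":"))]]$residual_sd,
      ks_D = ks$D, ks_p = ks$p,
      test_accuracy_pct = suppressWarnings(test_accuracy(p)),
      mad_cm = mean_absolute_deviation(p$point_cm, p$known_cm),
      bias_cm = ba$bias_cm, lower_limit_cm = ba$lower_limit_cm,
      upper_limit_cm = ba$upper_limit_cm)
  })
  out <- list_rbind(rows)
  if (keep_predictions) attr(out, "predictions") <- preds
  out
}

#' Cross-tabulate misclassifications by measurement and model type
#'
#' A misclassification is a prediction whose interval does not contain the
#' known stature. For each (model type x measurement group) cell the table
#' reports the percent among ALL predictions and the percent among
#' misclassifications only, plus marginal totals and the number of
#' individuals with at least one misclassification.
#'
#' @param predictions Per-prediction tibble with `family`, `measurement`,
#'   `id`, interval bounds and `known_cm` — e.g. the `"predictions"`
#'   attribute of [evaluate_models()] run with `keep_predictions = TRUE`.
#' @return An object of class `misclassification_report`: a list with
#'   `cells` (tibble: `model_type`, `group`, `n`, `n_misclassified`,
#'   `pct_of_all`, `pct_of_misclassified`), `by_model_type` and `by_group`
#'   marginals, `n_predictions`, `n_misclassified`, `overall_pct`, and
#'   `n_individuals_misclassified`.
#' @export
misclassification_report <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  need <- c("family", "measurement", "id", "pi_lower_cm", "pi_upper_cm", "known_cm")
  if (!all(need %in% names(predictions))) {
    abort(paste("predictions must carry:", paste(need, collapse = ", ")))
  }
  p <- predictions
  p$misclassified <- !(p$known_cm >= p$pi_lower_cm & p$known_cm <= p$pi_upper_cm)
  p$model_type <- ifelse(p$family == "linear", "linear", "nonlinear")
  p$group <- measurement_group(p$measurement)
  n_total <- nrow(p)
  n_mis <- sum(p$misclassified)
  tab <- function(df, ...) {
    df %>%
      group_by(...) %>%
      summarise(n = dplyr::n(), n_misclassified = sum(.data$misclassified), .groups = "drop") %>%
      mutate(
        pct_of_all = 100 * .data$n_misclassified / n_total,
        pct_of_misclassified = if (n_mis > 0) 100 * .data$n_misclassified / n_mis else 0
      )
  }
  structure(
    list(
      cells = tab(p, .data$model_type, .data$group),
      by_model_type = tab(p, .data$model_type),
      by_group = tab(p, .data$group),
      n_predictions = n_total,
      n_misclassified = n_mis,
      overall_pct = round(100 * n_mis / n_total, 2),
      n_individuals_misclassified = dplyr::n_distinct(p$id[p$misclassified])
    ),
    class = "misclassification_report"
  )
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat(sprintf("Misclassifications: %d of %d predictions (%.2f%%); %d individual(s) with >= 1\n",
              x$n_misclassified, x$n_predictions, x$overall_pct,
              x$n_individuals_misclassified))
  wide <- x$cells %>%
    mutate(cell = sprintf("%.2f (%.1f)", .data$pct_of_all, .data$pct_of_misclassified)) %>%
    select("model_type", "group", "cell") %>%
    pivot_wider(names_from = "group", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  cat("cell: % of all predictions (% of misclassifications)\n")
  invisible(x)
}
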