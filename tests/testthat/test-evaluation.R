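test_that("train/test split is disjoint, exhaustive, sized by round(n * frac)", {
  d <- tibble::tibble(id = as.character(1:10), v = 1:10)
  sp <- train_test_split(d, seed = 1)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), d$id)
  # determinism: same seed, same membership
  sp2 <- train_test_split(d, seed = 1)
  expect_identical(sp$train$id, sp2$train$id)
  # n = 990 gives round(792)/198 under this rule
  big <- tibble::tibble(id = as.character(1:990))
  spb <- train_test_split(big, seed = 2)
  expect_equal(nrow(spb$train), 792)
  expect_equal(nrow(spb$test), 198)
  expect_error(train_test_split(d[1:3, ], seed = 1), "at least 5")
  expect_error(train_test_split(d, train_frac = 1.2, seed = 1), "train_frac")
})

test_that("MAD is the mean absolute error", {
  expect_equal(mean_absolute_deviation(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_absolute_deviation(c(100, 110), c(102, 106)), 3)
  expect_equal(mean_absolute_deviation(105, 100), 5)
  expect_error(mean_absolute_deviation(1:3, 1:2), "equal length")
})

test_that("KS statistic matches hand cases and the brute-force ECDF sweep", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$D, 0.5)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
  set.seed(55)
  for (rep in 1:100) {
    a <- round(rnorm(sample(2:50, 1), 100, 10), 1)
    b <- round(rnorm(sample(2:50, 1), 102, 12), 1)
    expect_equal(ks_two_sample(a, b)$D, brute_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("Kendall tau-b matches hand cases and O(n^2) pair counting", {
  expect_equal(kendall_tau(1:5, 2 * (1:5)), 1)
  expect_equal(kendall_tau(1:5, rev(1:5)), -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "all tied")
  set.seed(56)
  for (rep in 1:100) {
    n <- sample(3:100, 1)
    x <- sample(1:20, n, replace = TRUE)   # ties on purpose
    y <- x + sample(-3:3, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau(x, y), brute_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("test accuracy counts interval coverage, excluding unavailable rows", {
  res <- tibble::tibble(
    pi_lower_cm = c(90, 90, 90, 90), pi_upper_cm = c(110, 110, 110, 110),
    known_cm = c(100, 95, 120, 108), method = "exact_t"
  )
  expect_equal(test_accuracy(res), 75.0)
  expect_equal(test_accuracy(dplyr::mutate(res, known_cm = 100)), 100.0)
  expect_equal(test_accuracy(dplyr::mutate(res, known_cm = 500)), 0.0)
  res$method[1] <- "unavailable"
  expect_warning(acc <- test_accuracy(res), "unavailable")
  expect_equal(acc, round(100 * 2 / 3, 1))
})

test_that("Bland-Altman bias and limits of agreement", {
  ba <- bland_altman(c(101, 99), c(100, 100))
  expect_equal(ba$bias_cm, 0)
  expect_equal(ba$upper_limit_cm, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$lower_limit_cm, -1.96 * sqrt(2), tolerance = 1e-12)
  ba2 <- bland_altman(c(102, 103), c(100, 101))
  expect_equal(unlist(ba2), c(bias_cm = 2, lower_limit_cm = 2, upper_limit_cm = 2))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("agreement metrics are invariant to case order", {
  set.seed(57)
  pred <- rnorm(40, 150, 10); known <- pred + rnorm(40, 0, 3)
  perm <- sample(40)
  expect_equal(mean_absolute_deviation(pred, known),
               mean_absolute_deviation(pred[perm], known[perm]))
  expect_equal(bland_altman(pred, known), bland_altman(pred[perm], known[perm]))
  res <- tibble::tibble(pi_lower_cm = pred - 5, pi_upper_cm = pred + 5,
                        known_cm = known, method = "exact_t")
  expect_equal(test_accuracy(res), test_accuracy(res[perm, ]))
})

test_that("evaluate_models mirrors the published validation table layout", {
  cohort <- simulate_cohort(600, seed = 19)
  sp <- train_test_split(cohort, seed = 20)
  fits <- fit_stature_models(sp$train)
  ev <- evaluate_models(fits, sp$test, keep_predictions = TRUE)
  expect_equal(nrow(ev), sum(fits$converged))
  expect_true(all(c("kendall_tau", "residual_sd_cm", "ks_D", "ks_p",
                    "test_accuracy_pct", "mad_cm", "bias_cm",
                    "lower_limit_cm", "upper_limit_cm") %in% names(ev)))
  expect_true(all(ev$kendall_tau > 0.7))
  expect_true(all(ev$ks_p >= 0 & ev$ks_p <= 1))
  expect_true(all(ev$lower_limit_cm <= ev$bias_cm & ev$bias_cm <= ev$upper_limit_cm))
  preds <- attr(ev, "predictions")
  expect_true(all(c("id", "known_cm", "family", "measurement") %in% names(preds)))
})

test_that("a noiseless generative pipeline predicts stature almost exactly", {
  cohort <- simulate_cohort(300, seed = 23, config = noiseless_config())
  sp <- train_test_split(cohort, seed = 24)
  fits <- fit_stature_models(sp$train)
  nl <- fits[fits$family != "linear", ]
  ev <- evaluate_models(nl, sp$test)
  expect_lt(max(ev$mad_cm), 1e-6)
  # degenerate exact predictions: zero MAD and KS distance, full coverage
  known <- sp$test$stature_cm
  expect_equal(mean_absolute_deviation(known, known), 0)
  expect_equal(ks_two_sample(known, known)$D, 0)
  expect_equal(test_accuracy(tibble::tibble(
    pi_lower_cm = known, pi_upper_cm = known, known_cm = known
  )), 100.0)
})

test_that("misclassification table percentages are coherent", {
  # build a prediction set with known per-cell misclassification counts
  cells <- expand.grid(
    family = c("linear", "nonlinear"),
    group = c("length", "proximal_breadth", "midshaft_breadth", "distal_breadth"),
    stringsAsFactors = FALSE
  )
  cells$n <- c(1000, 1000, 800, 800, 850, 850, 700, 675)
  cells$bad <- c(52, 39, 13, 33, 39, 48, 41, 31)
  rows <- purrr::pmap(cells, function(family, group, n, bad) {
    tibble::tibble(
      id = paste0(family, group, seq_len(n)),
      family = if (family == "linear") "linear" else "logistic3",
      measurement = group,
      pi_lower_cm = 90, pi_upper_cm = 110,
      known_cm = c(rep(200, bad), rep(100, n - bad))
    )
  })
  preds <- purrr::list_rbind(rows)
  rep <- misclassification_report(preds)
  expect_equal(rep$n_predictions, 6675)
  expect_equal(rep$n_misclassified, 296)
  expect_equal(rep$overall_pct, 4.43)
  # the two percentages per cell aggregate consistently
  expect_equal(sum(rep$cells$pct_of_all), 100 * rep$n_misclassified / rep$n_predictions)
  expect_equal(sum(rep$cells$pct_of_misclassified), 100)
  lin <- rep$by_model_type[rep$by_model_type$model_type == "linear", ]
  expect_equal(lin$pct_of_all, 2.17, tolerance = 0.003)
  expect_equal(lin$pct_of_misclassified, 49.0, tolerance = 0.001)
  # zero misclassifications: all cells zero
  clean <- dplyr::mutate(preds, known_cm = 100)
  rep0 <- misclassification_report(clean)
  expect_equal(rep0$n_misclassified, 0)
  expect_equal(rep0$n_individuals_misclassified, 0)
  expect_true(all(rep0$cells$pct_of_all == 0))
})
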