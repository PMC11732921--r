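test_that("hand-worked linear prediction interval is reproduced exactly", {
  f <- fit_linear(c(0, 1, 2), c(0, 2, 2))
  p <- prediction_interval(f, 1, level = 0.95)
  expect_equal(p$point_cm, 4 / 3)
  half <- qt(0.975, df = 1) * sqrt(2 / 3) * sqrt(1 + 1 / 3)
  expect_equal(p$pi_upper_cm - p$point_cm, half)
  expect_equal(p$point_cm - p$pi_lower_cm, half)
  expect_equal(half, 12.7062 * sqrt(2 / 3) * sqrt(4 / 3), tolerance = 1e-5)
  expect_equal(p$method, "exact_t")
})

test_that("zero residual noise collapses the interval to the point", {
  f <- fit_linear(c(1, 2, 3, 4), c(3, 5, 7, 9))
  p <- prediction_interval(f, 2.5)
  expect_equal(p$pi_lower_cm, p$point_cm)
  expect_equal(p$pi_upper_cm, p$point_cm)
})

test_that("large-n interval at the training mean approaches the z limit", {
  m <- stature_model("humerus", "length", "linear", c(a = 0.5, b = 20),
                     n = 1e6, residual_sd = 1, x_mean = 300, sxx = 1e9,
                     source = "fitted")
  p <- prediction_interval(m, 300)
  expect_equal(p$pi_upper_cm - p$point_cm, 1.959964, tolerance = 1e-4)
})

test_that("higher level strictly widens the interval", {
  gen <- ex_asymexp()
  xy <- simulate_xy(gen, 200, c(50, 350), 3, seed = 8)
  f <- fit_nonlinear(gen$family, xy$x, xy$y)
  p95 <- prediction_interval(f, 200, level = 0.95)
  p99 <- prediction_interval(f, 200, level = 0.99)
  expect_lt(p99$pi_lower_cm, p95$pi_lower_cm)
  expect_gt(p99$pi_upper_cm, p95$pi_upper_cm)
  expect_error(prediction_interval(f, 200, level = 0.3), "level")
})

test_that("delta-method intervals achieve nominal coverage on well-specified data", {
  gen <- ex_asymexp()
  train <- simulate_xy(gen, 500, c(50, 350), 4.6, seed = 42)
  test <- simulate_xy(gen, 2000, c(50, 350), 4.6, seed = 4242)
  f <- fit_nonlinear("asymptotic_exponential", train$x, train$y)
  p <- prediction_interval(f, test$x, level = 0.95)
  coverage <- 100 * mean(test$y >= p$pi_lower_cm & test$y <= p$pi_upper_cm)
  expect_gte(coverage, 93.5)
  expect_lte(coverage, 96.5)
  expect_true(all(p$method == "delta_t"))
})

test_that("bootstrap and delta-method half-widths agree on well-specified data", {
  gen <- ex_linear()
  xy <- simulate_xy(gen, 500, c(100, 400), 4, seed = 21)
  f <- fit_linear(xy$x, xy$y)
  x0 <- 250
  delta <- prediction_interval(f, x0)
  boot <- prediction_interval(f, x0, method = "bootstrap", B = 400, seed = 22)
  hw_d <- (delta$pi_upper_cm - delta$pi_lower_cm) / 2
  hw_b <- (boot$pi_upper_cm - boot$pi_lower_cm) / 2
  expect_equal(hw_b, hw_d, tolerance = 0.1)
  expect_equal(boot$method, "bootstrap")
})

test_that("registry predictions fall back to the approximate z interval", {
  reg <- load_registry()
  m <- reg$model[[which(reg$bone == "humerus" & reg$measurement == "length" &
                          reg$family == "linear")]]
  p <- prediction_interval(m, 300)
  expect_equal(p$method, "approx_z")
  expect_equal(p$pi_upper_cm - p$point_cm, qnorm(0.975) * 5.56)
  expect_match(unlist(p$warnings), "approximate", all = FALSE)
})

test_that("extrapolation warns but never refuses", {
  f <- fit_linear(c(100, 200, 300, 400), c(80, 120, 155, 175))
  p <- prediction_interval(f, 900)
  expect_match(unlist(p$warnings), "extrapolation")
  expect_true(is.finite(p$point_cm))
  expect_equal(length(unlist(prediction_interval(f, 250)$warnings)), 0)
})

test_that("estimate_stature returns both registry models for a lone humerus", {
  case <- tibble::tibble(id = "x1", humerus_length_mm = 300)
  est <- estimate_stature(case)
  expect_equal(nrow(est), 2)
  lin <- est[est$family == "linear", ]
  nl <- est[est$family != "linear", ]
  expect_equal(lin$point_cm, 163.3)
  expect_equal(nl$point_cm, 337 - 329 * exp(-0.00214 * 300), tolerance = 1e-10)
  expect_equal(round(nl$point_cm, 1), 163.9)
  # nonlinear first: its printed MAD (3.99) beats the linear 5.54
  expect_equal(est$family[1], "asymptotic_exponential")
})

test_that("estimate_stature uses composites and honours family selection", {
  case <- tibble::tibble(id = "x2", humerus_length_mm = 300,
                         radius_length_mm = 220, femur_length_mm = 400,
                         tibia_length_mm = 330)
  est <- estimate_stature(case)
  expect_equal(nrow(est), 12)  # 6 usable measurements x 2 families
  expect_setequal(unique(est$bone),
                  c("humerus", "radius", "femur", "tibia", "upper_limb", "lower_limb"))
  expect_equal(nrow(estimate_stature(case, families = "linear")), 6)
  one <- estimate_stature(case, families = "nonlinear_first")
  expect_equal(nrow(one), 6)
  expect_true(all(one$family == "asymptotic_exponential"))
  # no usable measurements -> empty result with a message
  expect_message(out <- estimate_stature(tibble::tibble(id = "e")), "No measurement")
  expect_equal(nrow(out), 0)
})

test_that("sanity-flagged registry models tag their estimates", {
  case <- tibble::tibble(id = "x3", tibia_midshaft_breadth_mm = 25)
  est <- estimate_stature(case, families = "nonlinear")
  expect_equal(nrow(est), 1)
  expect_match(unlist(est$warnings), "sanity-flagged", all = FALSE)
})
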