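test_that("measurement dictionary covers 18 single + 2 composite measurements", {
  dict <- measurement_dictionary()
  expect_equal(nrow(dict), 20)
  expect_equal(sum(dict$composite), 2)
  expect_true(all(dict$measurement[dict$composite] == "length"))
  # ulna has no proximal/distal breadth; femur no proximal; fibula length only
  expect_equal(sum(dict$bone == "ulna"), 2)
  expect_equal(sum(dict$bone == "femur"), 3)
  expect_equal(sum(dict$bone == "fibula"), 1)
  expect_false(any(dict$bone == "ulna" & dict$measurement == "proximal_breadth"))
})

test_that("evaluate_model reproduces the family formulas", {
  expect_equal(evaluate_model(ex_linear(), 300), 163.3)
  # at x -> 0+, exp(-cx) -> 1 so the asymptotic exponential tends to a - b
  expect_equal(evaluate_model(ex_asymexp(), 1e-12), 8, tolerance = 1e-6)
  # logistic approaches its asymptote a for large x
  expect_equal(evaluate_model(ex_logistic(), 1e5), 209)
  expect_equal(evaluate_model(
    stature_model("femur", "length", "asymptotic_exponential",
                  c(a = 366, b = 345, c = 0.00127)), 450),
    171.2, tolerance = 0.05 / 171.2)
})

test_that("evaluate_model rejects bad input but never returns NaN", {
  m <- ex_asymexp()
  expect_error(evaluate_model(m, -5), "finite and > 0")
  expect_error(evaluate_model(m, NA_real_), "finite and > 0")
  expect_error(evaluate_model(m, Inf), "finite and > 0")
  # a negative rate constant would overflow exp(-c x): clamped, never NaN
  weird <- stature_model("humerus", "length", "asymptotic_exponential",
                         c(a = 100, b = 1, c = -10))
  expect_false(is.nan(evaluate_model(weird, 600)))
})

family_eval_test <- function(fam, co, x) {
  switch(fam,
    linear = co[["a"]] * x + co[["b"]],
    asymptotic_exponential = co[["a"]] - co[["b"]] * exp(-co[["c"]] * x),
    logistic3 = co[["a"]] / (1 + co[["b"]] * exp(-co[["c"]] * x))
  )
}

test_that("analytic gradients match central finite differences", {
  set.seed(421)
  for (rep in 1:25) {
    fam <- sample(c("linear", "asymptotic_exponential", "logistic3"), 1)
    co <- switch(fam,
      linear = c(a = runif(1, 0.1, 10), b = runif(1, -20, 40)),
      asymptotic_exponential = c(a = runif(1, 150, 400), b = runif(1, 100, 390),
                                 c = runif(1, 0.001, 0.01)),
      logistic3 = c(a = runif(1, 150, 250), b = runif(1, 5, 20),
                    c = runif(1, 0.02, 0.3))
    )
    m <- stature_model("humerus", if (fam == "asymptotic_exponential") "length" else "midshaft_breadth",
                       fam, co)
    x <- runif(1, 5, if (fam == "asymptotic_exponential") 400 else 70)
    g <- drop(model_gradient(m, x))
    fd <- vapply(seq_along(co), function(k) {
      h <- 1e-4 * abs(co[k])
      up <- co; up[k] <- up[k] + h
      dn <- co; dn[k] <- dn[k] - h
      (family_eval_test(fam, up, x) - family_eval_test(fam, dn, x)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), fd, tolerance = 1e-5)
  }
})

test_that("gradient closed forms at simple points", {
  m <- ex_linear()
  expect_equal(unname(drop(model_gradient(m, 7))), c(7, 1))
  g <- drop(model_gradient(ex_asymexp(), 1e-12))
  expect_equal(unname(g), c(1, -1, 329 * 1e-12), tolerance = 1e-6)
})

test_that("invert_model round-trips and rejects out-of-range statures", {
  expect_equal(invert_model(ex_linear(), 163.3), 300)
  expect_equal(invert_model(ex_logistic(), 209 / 2), log(10.8) / 0.153,
               tolerance = 1e-10)
  expect_error(invert_model(ex_asymexp(), 337), "attainable range")
  expect_error(invert_model(ex_asymexp(), 2), "attainable range")
  # property: evaluate(invert(y)) == y across every registry model
  reg <- load_registry()
  set.seed(99)
  for (i in seq_len(nrow(reg))) {
    m <- reg$model[[i]]
    rng <- if (m$family == "linear") c(60, 190) else {
      lims <- sort(c(staturekit:::model_y_range(m)))
      c(lims[1] + 0.05 * diff(lims), lims[2] - 0.05 * diff(lims))
    }
    y <- runif(100, rng[1], rng[2])
    expect_lt(max(abs(evaluate_model(m, invert_model(m, y)) - y)), 1e-9)
  }
})

test_that("registry curves are increasing over the measurement range", {
  reg <- load_registry()
  grid <- seq(1, 699, by = 2)
  for (i in seq_len(nrow(reg))) {
    m <- reg$model[[i]]
    info <- paste(reg$bone[i], reg$measurement[i], reg$family[i])
    # never decreasing anywhere on (0, 700) mm
    expect_true(all(diff(evaluate_model(m, grid)) >= 0), info = info)
    # strictly increasing until the curve numerically saturates
    x_hi <- if (m$family == "linear") 699 else {
      rng <- staturekit:::model_y_range(m)
      min(699, invert_model(m, rng[2] - 1e-9 * diff(rng)))
    }
    strict <- seq(1, x_hi, length.out = 200)
    expect_true(all(diff(evaluate_model(m, strict)) > 0), info = info)
  }
})

test_that("composite limb lengths are sums, never overwrites, tolerate absence", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      humerus_length_mm = c(300, 310, NA),
                      radius_length_mm = c(220, NA, 230),
                      femur_length_mm = c(400, 410, 420),
                      tibia_length_mm = c(330, 340, 350))
  out <- add_composite_lengths(d)
  expect_equal(out$upper_limb_length_mm, c(520, NA, NA))
  expect_equal(out$lower_limb_length_mm, c(730, 750, 770))
  expect_equal(ncol(out), ncol(d) + 2)
  # pre-existing composite values are kept
  d$upper_limb_length_mm <- c(999, NA, NA)
  out2 <- add_composite_lengths(d)
  expect_equal(out2$upper_limb_length_mm[1], 999)
})
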