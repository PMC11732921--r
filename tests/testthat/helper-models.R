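# shared fixtures: example models and small oracle implementations

ex_linear <- function() {
  stature_model("humerus", "length", "linear", c(a = 0.46, b = 25.3))
}

ex_asymexp <- function() {
  stature_model("humerus", "length", "asymptotic_exponential",
                c(a = 337, b = 329, c = 0.00214))
}

ex_logistic <- function() {
  stature_model("femur", "midshaft_breadth", "logistic3",
                c(a = 209, b = 10.8, c = 0.153))
}

# a plausible x range for generating data from a model
ex_x_range <- function(model) {
  if (model$measurement == "length") {
    if (model$bone %in% c("upper_limb", "lower_limb")) c(100, 800) else c(50, 400)
  } else {
    c(5, 70)
  }
}

# brute-force two-sample KS distance: sup |ECDF_a - ECDF_b| over all points
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# O(n^2) tie-corrected Kendall tau-b by explicit pair counting
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - count_ties(x)) * (n0 - count_ties(y)))
}

count_ties <- function(v) {
  tab <- table(v)
  sum(tab * (tab - 1) / 2)
}

# closed-form OLS via the normal equations
brute_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - slope * x - intercept)^2)
  list(slope = slope, intercept = intercept,
       residual_sd = sqrt(sse / (length(x) - 2)))
}

# noiseless simulation configuration (exact generative round trips)
noiseless_config <- function() {
  simulation_config(stature_noise_sd = function(age) 0,
                    measurement_noise_frac = 0)
}
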