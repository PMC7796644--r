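test_that("cumulative dose sums strictly-past doses", {
  h <- dose_history(c(0, 14, 28), 1)
  expect_equal(cumulative_exposure(h, 30), 3)
  # a dose given at t itself does not count at t
  expect_equal(cumulative_exposure(h, 14), 1)
  expect_equal(cumulative_exposure(dose_history(), 100), 0)
  # vectorized, right-continuous steps
  expect_equal(cumulative_exposure(h, c(0, 0.5, 14, 14.5, 100)),
               c(0, 1, 1, 2, 3))
})

test_that("cumulative dose is non-decreasing for random histories", {
  set.seed(41)
  for (i in 1:20) {
    h <- random_history()
    t <- sort(runif(50, -10, 500))
    expect_true(all(diff(cumulative_exposure(h, t)) >= 0))
  }
})

test_that("theoretical blood concentration follows half-life decay", {
  # one dose, one half-life elapsed
  expect_equal(tbc(dose_history(0, 5), 20, half_life = 20), 2.5)
  # worked three-dose value, checked against a direct evaluation of the
  # decay-weighted sum
  h <- dose_history(c(0, 15, 30), 5)
  direct <- 5 * (0.5^(30 / 20) + 0.5^(15 / 20) + 0.5^0)
  expect_equal(tbc(h, 30 + 1e-9, half_life = 20), direct, tolerance = 1e-6)
  expect_equal(round(direct, 3), 9.741)
  # infinite-half-life limit recovers the cumulative dose
  set.seed(7)
  for (i in 1:10) {
    h <- random_history()
    t <- runif(1, 0, 500)
    expect_equal(tbc(h, t, half_life = 1e9), cumulative_exposure(h, t),
                 tolerance = 1e-6)
  }
})

test_that("TBC is bounded by CE and decays exactly between doses", {
  set.seed(11)
  for (i in 1:10) {
    h <- random_history()
    t <- sort(runif(20, 1, 500))
    ce <- cumulative_exposure(h, t)
    conc <- tbc(h, t, 20)
    expect_true(all(conc >= 0 & conc <= ce + 1e-12))
  }
  h <- dose_history(c(0, 50), 1)
  # no dose in (10, 40]: pure decay by 0.5^(30/20)
  expect_equal(tbc(h, 40, 20), tbc(h, 10, 20) * 0.5^(30 / 20))
})

test_that("risk-set standardization yields mean-0 sd-1 z-scores", {
  expect_equal(standardize_exposure(c(2, 4, 6)), c(-1, 0, 1))
  expect_equal(standardize_exposure(c(5, 5, 5)), c(0, 0, 0))
  expect_error(standardize_exposure(3), "at least 2")
  set.seed(5)
  v <- rgamma(40, 2)
  z <- standardize_exposure(v)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("quantile categories follow the two published schemes", {
  # tertiles of the non-zero doses; ties to the lower category
  lab <- quantile_categories(c(1, 2, 3, 4, 5, 6), arm = rep("maintenance", 6),
                             scheme = "model3a")
  expect_equal(as.character(lab), c("T1", "T1", "T2", "T2", "T3", "T3"))
  # control reference and zero-dose maintenance categories
  lab <- quantile_categories(c(0, 0, 1, 2, 3), scheme = "model3a",
                             arm = c("control", "maintenance", "maintenance",
                                     "maintenance", "maintenance"))
  expect_equal(as.character(lab),
               c("control", "maintenance_zero", "T1", "T2", "T3"))
  expect_equal(levels(lab),
               c("control", "maintenance_zero", "T1", "T2", "T3"))
  # quartile scheme: zero doses fall in the lowest category
  lab <- quantile_categories(c(0, 1, 2, 3, 4, 5, 6, 7, 8), scheme = "model3b")
  expect_equal(as.character(lab)[1], "Q1")
  expect_equal(table(lab)[["Q1"]], 3L)  # the zero plus the lowest quartile
  # degenerate risk sets are refused, naming the time
  expect_error(quantile_categories(c(2, 2, 2, 2), arm = rep("maintenance", 4),
                                   scheme = "model3a", time = 33),
               "degenerate risk set at t=33")
  expect_error(quantile_categories(c(0, 1, 2), arm = rep("maintenance", 3),
                                   scheme = "model3a"), "degenerate")
})

test_that("category counts are balanced up to ties at each quantile split", {
  set.seed(13)
  v <- rgamma(60, 2) + 0.1
  lab <- quantile_categories(v, scheme = "model3b")
  expect_true(max(table(lab)) - min(table(lab)) <= 1)
  lab <- quantile_categories(v, arm = rep("maintenance", 60),
                             scheme = "model3a")
  expect_true(max(table(lab)[c("T1", "T2", "T3")]) -
                min(table(lab)[c("T1", "T2", "T3")]) <= 1)
})

test_that("spline basis has the expected dimension and partition of unity", {
  b <- make_spline_basis(120, n_interior_knots = 1)
  expect_equal(b$J, 5L)   # interior + degree + 1
  u <- seq(0, 120, length.out = 1000)
  expect_equal(rowSums(eval_basis(b, u)), rep(1, 1000))
  expect_equal(make_spline_basis(120, 2)$J, 6L)
  expect_equal(make_spline_basis(120, 3)$J, 7L)
  # outside the window the basis vanishes
  expect_equal(eval_basis(b, c(-1, 121)), matrix(0, 2, 5))
  expect_error(make_spline_basis(120, interior_knots = c(0, 50)), "strictly")
})

test_that("right-end constraint forces w(window) = 0", {
  b <- make_spline_basis(120, n_interior_knots = 1,
                         constrained_right_end = TRUE)
  expect_equal(b$J, 3L)   # two basis functions dropped
  set.seed(3)
  for (i in 1:5) {
    wf <- weight_function(rnorm(b$J), b)
    expect_equal(eval_weight(wf, 120), 0)
    # and the derivative vanishes too: value just inside is already tiny
    expect_lt(abs(eval_weight(wf, 119.999)), 1e-6)
  }
})

test_that("artificial covariates are the windowed dose-weighted basis sums", {
  b <- make_spline_basis(120, 2)
  set.seed(23)
  for (i in 1:10) {
    h <- random_history()
    t <- runif(3, 0, 500)
    D <- wce_artificial_covariates(h, b, t)
    # partition of unity => row sums equal the windowed cumulative dose
    windowed <- cumulative_exposure(h, t) - cumulative_exposure(h, t - 120)
    expect_equal(rowSums(D), windowed, tolerance = 1e-10)
    # linearity in the coefficients: any theta reproduces the weighted sum
    theta <- rnorm(b$J)
    wf <- weight_function(theta, b)
    manual <- vapply(t, function(tt) {
      lag <- tt - h$times
      keep <- lag > 0 & lag <= 120
      sum(h$doses[keep] * eval_weight(wf, lag[keep]))
    }, numeric(1))
    expect_equal(as.numeric(D %*% theta), manual, tolerance = 1e-10)
  }
  # a history entirely older than the window contributes nothing
  h <- dose_history(c(0, 10), 1)
  expect_equal(wce_artificial_covariates(h, b, 200), matrix(0, 1, b$J))
  # and linearity in the dose history
  h2 <- dose_history(h$times, 2 * h$doses)
  expect_equal(wce_artificial_covariates(h2, b, 50),
               2 * wce_artificial_covariates(h, b, 50))
})

test_that("exponential decay projects onto the basis to within spline error", {
  b <- make_spline_basis(120, 3)
  wf <- project_onto_basis(b, function(u) 0.5^(u / 20))
  u <- seq(0, 120, by = 1)
  expect_lt(max(abs(eval_weight(wf, u) - 0.5^(u / 20))), 0.01)
})
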