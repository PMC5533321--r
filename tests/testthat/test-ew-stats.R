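# direct-definition oracles used throughout this file
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, variance = sum((x - mu)^2) / (n - 1),
       skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3)
}
oracle_lag1 <- function(x) {
  n <- length(x)
  mu <- mean(x)
  num <- 0
  for (t in 1:(n - 1)) num <- num + (x[t] - mu) * (x[t + 1] - mu)
  num / sum((x - mu)^2)
}

test_that("moments match closed-form and sampling expectations", {
  m <- moments(1:5)
  expect_equal(m$mean, 3)
  expect_equal(m$variance, 2.5)
  expect_equal(m$skewness, 0)

  set.seed(1)
  z <- rnorm(1e5)
  mz <- moments(z)
  expect_lt(abs(mz$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(mz$excess_kurtosis), 3 * sqrt(24 / 1e5))

  mc <- moments(rep(2, 10))
  expect_equal(mc$variance, 0)
  expect_true(is.na(mc$skewness) && is.na(mc$excess_kurtosis))
  expect_error(moments(1:3), "at least 4")
})

test_that("estimators equal their brute-force definitions to 1e-10", {
  set.seed(42)
  for (n in c(10, 137, 1000)) {
    x <- rnorm(n) + seq_len(n) / n
    mo <- moments(x)
    or <- oracle_moments(x)
    for (f in names(or))
      expect_equal(mo[[f]], or[[f]], tolerance = 1e-10)
    expect_equal(lag1_autocorrelation(x), oracle_lag1(x),
                 tolerance = 1e-10)
  }
  # deterministic ramp, n = 1000
  r <- as.numeric(1:1000)
  expect_equal(lag1_autocorrelation(r), oracle_lag1(r), tolerance = 1e-12)
})

test_that("lag-1 autocorrelation has the expected limits", {
  alt <- rep(c(1, -1), 50)
  expect_lt(abs(lag1_autocorrelation(alt) - (-1)), 0.02)

  set.seed(3)
  expect_lt(abs(lag1_autocorrelation(rnorm(1e5))), 0.01)

  expect_true(is.na(lag1_autocorrelation(rep(1, 10))))
  expect_error(lag1_autocorrelation(c(1, 2)), "at least 3")
})

test_that("ensemble summaries pool correctly", {
  set.seed(7)
  x <- rnorm(500)
  one <- ensemble_ew(list(x), control_value = 1)
  expect_equal(one$mean, mean(x))
  expect_equal(one$variance, var(x))
  expect_equal(one$lag1_ac, lag1_autocorrelation(x))

  # duplicated traces leave pooled moments unchanged
  two <- ensemble_ew(list(x, x), control_value = 1)
  expect_equal(two$mean, one$mean)
  expect_equal(two$skewness, one$skewness)
  expect_equal(two$lag1_ac, one$lag1_ac)
  expect_identical(two$n_samples, 1000L)

  # AR(1) ensembles recover the theoretical lag-1 coefficient
  set.seed(11)
  ar <- lapply(1:50, function(i)
    as.numeric(arima.sim(list(ar = 0.8), n = 400)))
  s <- ensemble_ew(ar, control_value = 0)
  expect_lt(abs(s$lag1_ac - 0.8), 0.05)

  pr <- ensemble_ew(ar, control_value = 0, pooling = "per_run_mean")
  expect_lt(abs(pr$lag1_ac - 0.8), 0.05)
})

test_that("critical-point estimators locate maxima and jumps", {
  sw <- data.frame(control_value = c(1, 1.5, 2), variance = c(1, 5, 2),
                   mean = c(3, 2, 1))
  cp <- estimate_cp(sw, "max_variance")
  expect_equal(as.numeric(cp), 1.5)
  expect_false(attr(cp, "boundary"))

  sw2 <- data.frame(control_value = c(0.1, 0.2, 0.3, 0.4),
                    mean = c(1, 1, 0, 0), variance = c(1, 1, 1, 1))
  cp2 <- estimate_cp(sw2, "max_abs_mean_slope")
  expect_equal(as.numeric(cp2), 0.25)

  # ties break toward the smaller control value; edges are flagged
  sw3 <- data.frame(control_value = 1:4, variance = c(7, 2, 7, 1),
                    mean = 1:4)
  expect_equal(as.numeric(estimate_cp(sw3, "max_variance")), 1)
  expect_true(attr(estimate_cp(sw3, "max_variance"), "boundary"))

  expect_error(estimate_cp(sw[1:2, ], "max_variance"), "at least 3")
  expect_error(estimate_cp(data.frame(control_value = c(1, 1, 2),
                                      variance = 1:3), "max_variance"),
               "strictly increasing")
})

test_that("alignment translates control axes so CPs coincide", {
  mk <- function(controls, vars) {
    structure(list(summaries = data.frame(control_value = controls,
                                          variance = vars,
                                          mean = seq_along(controls)),
                   cp_estimate = controls[which.max(vars)],
                   cp_method = "max_variance", cp_boundary = FALSE,
                   aligned = FALSE, shift = 0),
              class = "sweep_summary")
  }
  a <- mk(c(1.2, 1.6, 2.0), c(1, 9, 2))
  b <- mk(c(1.7, 2.1, 2.5), c(1, 8, 3))
  al <- align_to_cp(list(a, b))
  expect_equal(al[[1]]$summaries$control_value, c(-0.4, 0, 0.4))
  expect_equal(al[[2]]$summaries$control_value, c(-0.4, 0, 0.4))
  expect_true(all(vapply(al, `[[`, logical(1), "aligned")))
  expect_equal(al[[1]]$shift, -1.6)

  z <- mk(c(-0.5, 0, 0.5), c(1, 5, 1))   # already centred: identity shift
  expect_equal(align_to_cp(z)[[1]]$summaries$control_value,
               c(-0.5, 0, 0.5))

  bd <- mk(c(1, 2, 3), c(9, 2, 1))
  bd$cp_boundary <- TRUE
  expect_warning(align_to_cp(bd), "boundary")
})
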