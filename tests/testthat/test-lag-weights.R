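test_that("lag profiles are nonnegative and sum to one", {
  p <- lag_profile(c(2, 1, 1))
  expect_equal(sum(p$weights), 1, tolerance = 1e-9)
  expect_identical(p$max_lag, 2L)
  expect_error(lag_profile(c(1, -0.1)), "nonnegative")
  expect_error(lag_profile(c(0, 0)), "all be zero")

  pm <- point_mass_profile(20)
  expect_identical(pm$max_lag, 20L)
  expect_equal(pm$weights[21], 1)
  expect_equal(sum(pm$weights), 1)
})

test_that("geometric weights have the closed form and decay monotonically", {
  g <- geometric_weights(1, 0.5)
  expect_equal(g$weights, c(2/3, 1/3))

  g20 <- geometric_weights(20, 0.9)
  expect_true(all(diff(g20$weights) < 0))
  expect_equal(sum(g20$weights), 1, tolerance = 1e-9)

  # decay -> 1 approaches the uniform profile
  gnear <- geometric_weights(10, 0.9999)
  expect_equal(gnear$weights, rep(1/11, 11), tolerance = 1e-3)

  expect_error(geometric_weights(10, 1), "decay")
  expect_error(geometric_weights(10, 0), "decay")
})

test_that("prewhiten with a white-noise exposure is the identity on differences", {
  set.seed(1)
  x <- annual_series(cumsum(rnorm(120)), 1900)  # differences are white noise
  y <- annual_series(cumsum(rnorm(120)), 1900)
  pw <- prewhiten(x, y)
  expect_identical(pw$ar_order, 0L)
  expect_equal(pw$x$values, diff(x$values))
  expect_equal(pw$y$values, diff(y$values))
})

test_that("prewhiten flattens an autocorrelated exposure to white noise", {
  white <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    dx <- as.numeric(stats::arima.sim(list(ar = 0.8), n = 200))
    x <- annual_series(cumsum(dx), 1800)  # differenced series is AR(1), 0.8
    y <- annual_series(cumsum(rnorm(200)), 1800)
    pw <- prewhiten(x, y)
    lb <- ljung_box_q10(pw$x$values)
    white <- white + (lb$p_value > 0.05)
  }
  expect_gte(white / 20, 0.9)

  expect_error(prewhiten(annual_series(rep(5, 50), 1900),
                         annual_series(rnorm(50), 1900)), "constant")
  expect_error(prewhiten(annual_series(rnorm(10), 1900),
                         annual_series(rnorm(10), 1900)), "30")
})

test_that("cross_correlate computes the 2/sqrt(n) band and finds a pure lag", {
  set.seed(9)
  # n = 69 overlapping pairs -> the 0.240 critical band
  cc69 <- cross_correlate(rnorm(69), rnorm(69), max_lag = 10)
  expect_identical(cc69$n_effective, 69L)
  expect_equal(cc69$critical_value, 2 / sqrt(69))
  expect_lt(abs(cc69$critical_value - 0.240), 1e-3)  # printed precision
  expect_identical(cc69$significant_lags,
                   cc69$lags[abs(cc69$ccf) > cc69$critical_value])

  # y_t = x_{t-3} exactly
  x <- rnorm(150)
  y <- c(rep(0, 3), x[1:147]) + rnorm(150, 0, 1e-8)
  cc <- cross_correlate(x[4:150], y[4:150], max_lag = 10)
  expect_equal(cc$ccf[4], 1, tolerance = 1e-3)
  expect_true(all(abs(cc$ccf[-4]) < 0.5))
  expect_identical(cc$lags[which.max(cc$ccf)], 3L)

  expect_error(cross_correlate(rep(1, 60), rnorm(60), 5), "zero-variance")
  expect_error(cross_correlate(rnorm(30), rnorm(30), 20), "half")
})

test_that("select_lag_length takes the largest significant positive lag", {
  fake <- function(ccf_vals, n = 69) {
    cc <- list(lags = 0:(length(ccf_vals) - 1L), ccf = ccf_vals,
               critical_value = 2 / sqrt(n), n_effective = n)
    cc$significant_lags <- cc$lags[abs(cc$ccf) > cc$critical_value]
    structure(cc, class = "ccf_result")
  }
  v <- rep(0.05, 26)
  v[c(2, 8, 21)] <- 0.3  # lags 1, 7, 20
  expect_identical(select_lag_length(fake(v)), 20L)

  expect_identical(select_lag_length(fake(rep(0.1, 26))), 0L)

  neg <- rep(-0.05, 26); neg[c(5, 15)] <- -0.4  # significant but negative
  expect_identical(select_lag_length(fake(neg)), 0L)
})

test_that("ccf_weights keeps significant positive lags, else falls back to uniform", {
  fake <- function(ccf_vals, n = 69) {
    cc <- list(lags = 0:(length(ccf_vals) - 1L), ccf = ccf_vals,
               critical_value = 2 / sqrt(n), n_effective = n)
    cc$significant_lags <- cc$lags[abs(cc$ccf) > cc$critical_value]
    structure(cc, class = "ccf_result")
  }
  v <- rep(0.01, 6); v[c(3, 5)] <- 0.3  # lags 2 and 4, equal
  w <- ccf_weights(fake(v), 5)
  expect_equal(w$weights, c(0, 0, 0.5, 0, 0.5, 0))

  v2 <- rep(0.01, 26); v2[21] <- 0.31
  w2 <- ccf_weights(fake(v2), 20)
  expect_equal(w2$weights[21], 1)

  w3 <- ccf_weights(fake(rep(0.01, 26)), 5)
  expect_identical(w3$scheme, "uniform")
  expect_equal(w3$weights, rep(1/6, 6))

  expect_error(ccf_weights(fake(rep(0.01, 26)), -1), ">= 0")
})

test_that("apply_weights is the lag-weighted moving sum with conserved level", {
  x <- annual_series(rnorm(30, 10), 1950)
  expect_equal(apply_weights(x, point_mass_profile(0))$values, x$values)

  cst <- annual_series(rep(7, 40), 1950)
  out <- apply_weights(cst, geometric_weights(15, 0.8))
  expect_equal(out$values, rep(7, 25), tolerance = 1e-12)
  expect_identical(out$start_year, 1965L)

  yrs <- annual_series(1950:1979, 1950)
  wa <- apply_weights(yrs, lag_profile(rep(1, 3), scheme = "uniform"))
  expect_equal(wa$values, (1952:1979) - 1)

  # point mass at k delays by exactly k
  pm <- apply_weights(x, point_mass_profile(4))
  expect_equal(pm$values, x$values[1:26])
  expect_identical(pm$start_year, 1954L)

  expect_error(apply_weights(annual_series(1:5, 2000), point_mass_profile(5)),
               "longer")
})
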