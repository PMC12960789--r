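test_that("sim_config enforces its invariants", {
  expect_error(sim_config(n_years = 45L), "lag length")
  expect_error(sim_config(noise_sd = 0), "positive")
  cfg <- sim_config(seed = 1)
  expect_identical(cfg$n_years, 109L)
  expect_identical(cfg$lag_profile_true$max_lag, 20L)
})

test_that("simulate_exposure honours shape and seed", {
  flat <- sim_config(seed = 1, exposure_shape = "flat", exposure_level = 10)
  expect_equal(simulate_exposure(flat)$values, rep(10, 109))

  cfg <- sim_config(seed = 12)
  a <- simulate_exposure(cfg)
  b <- simulate_exposure(cfg)
  expect_identical(a$values, b$values)
  c2 <- simulate_exposure(sim_config(seed = 13))
  expect_false(identical(a$values, c2$values))

  # paper-like shape peaks in the middle third
  for (s in 1:20) {
    e <- simulate_exposure(sim_config(seed = s))
    peak <- which.max(e$values)
    expect_gte(peak, 109 / 3)
    expect_lte(peak, 2 * 109 / 3)
    expect_true(all(e$values >= 0))
  }

  rw <- simulate_exposure(sim_config(seed = 3, exposure_shape = "random-walk"))
  expect_true(all(rw$values >= 0))
  expect_identical(length(rw$values), 109L)
})

test_that("simulate_mortality reduces to the null model without signal", {
  cfg <- sim_config(seed = 2, beta_true = 0, mu_tobacco = 0, mu_health = 0,
                    noise_sd = 1e-12, ma1_theta = 0)
  x <- simulate_exposure(cfg)
  m <- simulate_mortality(x, list(), cfg)
  expect_equal(m$values, rep(exp(cfg$baseline_log_mortality), length(m$values)),
               tolerance = 1e-8)
  expect_identical(m$start_year, x$start_year + 20L)
})

test_that("a flat exposure leaves mortality untouched by beta (differencing kills constants)", {
  cfg <- sim_config(seed = 2, beta_true = 0.035, exposure_shape = "flat",
                    noise_sd = 1e-12, ma1_theta = 0)
  x <- simulate_exposure(cfg)
  m <- simulate_mortality(x, list(), cfg)
  expect_equal(m$values, rep(exp(cfg$baseline_log_mortality), length(m$values)),
               tolerance = 1e-8)
})

test_that("in the noiseless limit OLS on differences recovers beta exactly", {
  cfg <- sim_config(seed = 5, noise_sd = 1e-12, ma1_theta = 0)
  x <- simulate_exposure(cfg)
  m <- simulate_mortality(x, list(), cfg)
  wa <- apply_weights(x, cfg$lag_profile_true)
  al <- align(log_series(m), wa)
  b <- stats::coef(stats::lm(diff(al[[1]]$values) ~ diff(al[[2]]$values)))[2]
  expect_equal(unname(b), cfg$beta_true, tolerance = 1e-8)
})

test_that("generated mortality is strictly positive across parameterisations", {
  grid <- expand.grid(beta = c(0, 0.035, 0.1), theta = c(0, 0.5),
                      sd = c(0.005, 0.05))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(seed = 600 + i, beta_true = grid$beta[i],
                      ma1_theta = grid$theta[i], noise_sd = grid$sd[i])
    sim <- simulate_study(cfg)
    for (s in sim$dataset$series)
      expect_true(all(s$values >= 0))
    m <- get_series(sim$dataset, "cancer", "all", "all")
    expect_true(all(m$values > 0))
  }
})

test_that("simulate_study writes a dataset CSV plus a truth sidecar", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_study(cfg, strata = data.frame(
    label = c("uadt", "lung"), sex = c("male", "male"),
    age_group = c("all", "all"), stringsAsFactors = FALSE),
    beta_by_stratum = c(0.035, 0))
  expect_length(sim$dataset$series, 5)  # 3 exposures + 2 outcomes
  stem <- tempfile("sim-")
  write_simulation(sim, stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$beta_true, c(0.035, 0))
  expect_equal(sum(truth$lag_weights), 1)
  back <- read_dataset(paste0(stem, ".csv"))
  expect_length(back$series, 5)
  # health starts 25 years after alcohol, mirroring the shorter records
  expect_identical(get_series(back, "health", "all", "n/a")$start_year,
                   cfg$start_year + 25L)
})
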