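# Shared fixtures built in code.

# small CSV dataset on disk; returns the path
write_fixture_csv <- function(df, dir = tempdir()) {
  path <- tempfile("dataset-", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a quick, fully deterministic ARIMAX fit on synthetic data for report tests
fixture_fit <- function(seed = 5, label = "cancer", sex = "all",
                        age_group = "all", spec = arima_spec(0, 1)) {
  cfg <- sim_config(seed = seed, n_years = 80L, lag_profile_true =
                      point_mass_profile(5L))
  x <- simulate_exposure(cfg)
  m <- simulate_mortality(x, list(), cfg, label = label, sex = sex,
                          age_group = age_group)
  wa <- apply_weights(x, cfg$lag_profile_true)
  fit_arimax(log_series(m), list(alcohol = wa), spec = spec,
             stratum = list(label = label, sex = sex, age_group = age_group))
}

# fit the full synthetic study (alcohol + tobacco + health) for one stratum,
# using the true lag profile; the workhorse of the recovery experiments
fit_synthetic_stratum <- function(cfg, label = "cancer", sex = "all",
                                  age_group = "all", beta = NULL,
                                  spec = arima_spec(0, 1)) {
  sim <- simulate_study(cfg,
                        strata = data.frame(label = label, sex = sex,
                                            age_group = age_group,
                                            stringsAsFactors = FALSE),
                        beta_by_stratum = beta)
  ds <- sim$dataset
  prof <- cfg$lag_profile_true
  exposures <- list(
    alcohol = apply_weights(get_series(ds, "alcohol", "all", "n/a"), prof),
    tobacco = apply_weights(get_series(ds, "tobacco", "all", "n/a"), prof),
    health = apply_weights(get_series(ds, "health", "all", "n/a"), prof))
  fit_arimax(log_series(get_series(ds, label, sex, age_group)), exposures,
             spec = spec)
}
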