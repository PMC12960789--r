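#' Configuration for the synthetic study generator
#'
#' Collects the ground-truth parameters of a simulated study. The defaults
#' mirror the study conditions the pipeline is meant for: 109 years of
#' exposure (as for a 1910-2018 consumption record), a per-litre log effect
#' of 0.035 on the primary outcome, a 20-year exposure lag, MA(1)
#' disturbances on the differenced log-mortality equation (the error
#' structure matching the dominant (0,1,1) fitted order), and a smooth
#' rise-plateau-decline exposure trend.
#'
#' @param seed integer seed; every stochastic element of the generator is
#'   derived from it.
#' @param n_years length of the exposure record (default 109).
#' @param start_year first exposure year (default 1910).
#' @param beta_true per-litre effect on log mortality (default 0.035).
#' @param mu_tobacco,mu_health covariate effects on log mortality per unit of
#'   the simulated covariates (defaults 0.05 and -0.02: smoking harmful,
#'   health spending protective).
#' @param lag_profile_true a [lag_profile()]; default a point mass at lag 20.
#' @param ma1_theta MA(1) parameter of the disturbance (default 0.3).
#' @param noise_sd innovation standard deviation on the differenced log scale
#'   (default 0.005, i.e. half-percent annual shocks to mortality).
#' @param alpha drift of the differenced equation (default 0).
#' @param baseline_log_mortality log mortality rate in the first outcome year
#'   (default `log(10)`, i.e. 10 deaths per 100,000).
#' @param exposure_shape `"paper-like"` (smooth rise-plateau-decline),
#'   `"random-walk"` (reflected random walk) or `"flat"`.
#' @param exposure_level mean exposure level in litres (default 10).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_years = 109L, start_year = 1910L,
                       beta_true = 0.035, mu_tobacco = 0.05,
                       mu_health = -0.02,
                       lag_profile_true = point_mass_profile(20L),
                       ma1_theta = 0.3, noise_sd = 0.005, alpha = 0,
                       baseline_log_mortality = log(10),
                       exposure_shape = c("paper-like", "random-walk", "flat"),
                       exposure_level = 10) {
  exposure_shape <- match.arg(exposure_shape)
  stopifnot(inherits(lag_profile_true, "lag_profile"))
  n_years <- as.integer(n_years)
  if (n_years < lag_profile_true$max_lag + 30L)
    stop("n_years must be at least the lag length + 30", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_years = n_years,
                 start_year = as.integer(start_year), beta_true = beta_true,
                 mu_tobacco = mu_tobacco, mu_health = mu_health,
                 lag_profile_true = lag_profile_true, ma1_theta = ma1_theta,
                 noise_sd = noise_sd, alpha = alpha,
                 baseline_log_mortality = baseline_log_mortality,
                 exposure_shape = exposure_shape,
                 exposure_level = exposure_level),
            class = "sim_config")
}

# internal: deterministic rise-plateau-decline trend on [0, 1]; peaks at 0.55
exposure_trend <- function(u, level) {
  level * (0.6 + 0.4 * exp(-((u - 0.55) / 0.18)^2))
}

#' Simulate a per-capita consumption series
#'
#' Generates an exposure series of the configured shape. `"paper-like"` is a
#' deterministic smooth rise to a mid-series peak and later decline (the
#' gross shape of twentieth-century per-capita alcohol consumption) plus
#' small seeded AR(1) noise; `"random-walk"` reflects a Gaussian random walk
#' off zero; `"flat"` is constant. Values are never negative.
#'
#' @param config a [sim_config()].
#' @param label,sex identity for the returned series.
#' @param seed_offset offset added to `config$seed` so covariates drawn from
#'   the same config are independent.
#' @return An [annual_series()] of `config$n_years` values.
#' @export
simulate_exposure <- function(config, label = "alcohol", sex = "all",
                              seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_years
  withr_seed <- config$seed + as.integer(seed_offset)
  old <- .Random.seed_guard(withr_seed)
  on.exit(old(), add = TRUE)
  v <- switch(config$exposure_shape,
    "flat" = rep(config$exposure_level, n),
    "random-walk" = {
      steps <- stats::rnorm(n - 1L, 0, 0.05 * config$exposure_level)
      abs(config$exposure_level + c(0, cumsum(steps)))
    },
    "paper-like" = {
      trend <- exposure_trend((seq_len(n) - 1) / (n - 1), config$exposure_level)
      ar_noise <- as.numeric(stats::arima.sim(
        model = list(ar = 0.6), n = n,
        innov = stats::rnorm(n, 0, 0.015 * config$exposure_level)))
      pmax(trend + ar_noise, 0)
    })
  annual_series(v, config$start_year, label = label,
                unit = "L ethanol per capita 15+", sex = sex,
                age_group = "n/a")
}

# internal: seed the RNG restorably
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a mortality series from the differenced semi-log model
#'
#' Runs the study's regression model forwards: builds the lag-weighted
#' exposure `WA_t` from the true lag profile, draws an MA(1) disturbance
#' `e_t = eps_t + theta * eps_{t-1}`, sets
#' `dlog M_t = alpha + beta * dWA_t + sum_i mu_i * dC_{i,t} + e_t`,
#' integrates from the baseline log mortality and exponentiates. The output
#' starts `max_lag` years after the exposure starts (earlier years cannot see
#' a full lag window). Generated mortality is strictly positive by
#' construction.
#'
#' @param exposure an [annual_series()], typically from [simulate_exposure()].
#' @param covariates named list of [annual_series()] covariates, supplied on
#'   their raw scale; each is lag-weighted with the true profile before it
#'   enters the equation (covariates act through the same latency window as
#'   the exposure). Coefficients are looked up as `config$mu_<name>`
#'   (`mu_tobacco`, `mu_health`); unmatched names get coefficient 0.
#' @param config a [sim_config()].
#' @param label,sex,age_group identity of the returned mortality series.
#' @param seed_offset RNG offset, as in [simulate_exposure()].
#' @return An [annual_series()] of mortality rates per 100,000.
#' @export
simulate_mortality <- function(exposure, covariates = list(), config,
                               label = "cancer", sex = "all",
                               age_group = "all", seed_offset = 1000L) {
  stopifnot(inherits(exposure, "annual_series"), inherits(config, "sim_config"))
  L <- config$lag_profile_true$max_lag
  if (length(exposure$values) < L + 2L)
    stop("exposure shorter than lag length + 2", call. = FALSE)
  wa <- apply_weights(exposure, config$lag_profile_true)
  # covariates act through the same lag window as the exposure
  covariates <- lapply(covariates, apply_weights, profile = config$lag_profile_true)
  from <- wa$start_year
  to <- end_year(wa)
  for (cv in covariates) {
    from <- max(from, cv$start_year)
    to <- min(to, end_year(cv))
  }
  if (to - from < 2L) stop("covariates leave too few overlapping years",
                           call. = FALSE)
  wa <- window_series(wa, from, to)
  dwa <- diff(wa$values)
  n_d <- length(dwa)
  drive <- config$alpha + config$beta_true * dwa
  for (nm in names(covariates)) {
    mu <- config[[paste0("mu_", nm)]]
    if (is.null(mu)) mu <- 0
    cv <- window_series(covariates[[nm]], from, to)
    drive <- drive + mu * diff(cv$values)
  }
  old <- .Random.seed_guard(config$seed + as.integer(seed_offset))
  on.exit(old(), add = TRUE)
  eps <- stats::rnorm(n_d + 1L, 0, config$noise_sd)
  e <- eps[-1L] + config$ma1_theta * eps[-(n_d + 1L)]
  logm <- config$baseline_log_mortality + c(0, cumsum(drive + e))
  annual_series(exp(logm), from, label = label,
                unit = "deaths per 100,000", sex = sex, age_group = age_group)
}

#' Simulate a complete study dataset with known ground truth
#'
#' Convenience wrapper producing a [study_dataset()] shaped like the real
#' study: an alcohol exposure, a tobacco and a health-expenditure covariate
#' (independent seeds, the health series starting 25 years later as the
#' historical one does), and one mortality outcome per requested stratum
#' generated from the model with the configured ground truth. The returned
#' object carries the generating config in its metadata-adjacent `truth`
#' field.
#'
#' @param config a [sim_config()].
#' @param strata data frame with columns `label`, `sex`, `age_group`; default
#'   a single all-persons outcome named `"cancer"`.
#' @param beta_by_stratum optional numeric vector (recycled) of per-stratum
#'   alcohol effects overriding `config$beta_true` — e.g. 0 for a
#'   negative-control outcome.
#' @return List with `dataset` (a `study_dataset`) and `truth` (the config
#'   plus per-stratum betas).
#' @export
simulate_study <- function(config,
                           strata = data.frame(label = "cancer", sex = "all",
                                               age_group = "all",
                                               stringsAsFactors = FALSE),
                           beta_by_stratum = NULL) {
  stopifnot(inherits(config, "sim_config"))
  alcohol <- simulate_exposure(config, label = "alcohol", seed_offset = 0L)
  tobacco <- simulate_exposure(config, label = "tobacco", seed_offset = 101L)
  tobacco$unit <- "kg per capita 15+"
  health_cfg <- config
  health_cfg$n_years <- config$n_years - 25L
  health_cfg$start_year <- config$start_year + 25L
  health <- simulate_exposure(health_cfg, label = "health", seed_offset = 202L)
  health$unit <- "PPP$ per capita (scaled)"
  covars <- list(tobacco = tobacco, health = health)
  betas <- if (is.null(beta_by_stratum)) rep(config$beta_true, nrow(strata))
           else rep_len(beta_by_stratum, nrow(strata))
  outcomes <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    cfg_i <- config
    cfg_i$beta_true <- betas[i]
    outcomes[[i]] <- simulate_mortality(
      alcohol, covars, cfg_i, label = strata$label[i], sex = strata$sex[i],
      age_group = strata$age_group[i], seed_offset = 1000L + 17L * i)
  }
  ds <- study_dataset(c(list(alcohol, tobacco, health), outcomes),
                      metadata = list(generator = "alcomort::simulate_study",
                                      seed = config$seed))
  list(dataset = ds,
       truth = list(config = config, strata = strata, beta = betas))
}

#' Write a simulated dataset and its ground-truth sidecar
#'
#' @param sim result of [simulate_study()].
#' @param path output stem; writes `<path>.csv` (the dataset) and
#'   `<path>_truth.json` (true betas, lag profile, noise parameters).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_dataset(sim$dataset, paste0(path, ".csv"))
  cfg <- sim$truth$config
  truth <- list(seed = cfg$seed, beta_true = sim$truth$beta,
                strata = sim$truth$strata,
                mu_tobacco = cfg$mu_tobacco, mu_health = cfg$mu_health,
                ma1_theta = cfg$ma1_theta, noise_sd = cfg$noise_sd,
                lag_weights = cfg$lag_profile_true$weights,
                lag_scheme = cfg$lag_profile_true$scheme)
  jsonlite::write_json(truth, paste0(path, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
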