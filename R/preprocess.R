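#' Natural log transform of an annual series
#'
#' The outcome side of the semi-log model: mortality rates enter the
#' regression as natural logarithms, so a coefficient on an untransformed
#' exposure is a proportional (percentage) effect.
#'
#' @param s an [annual_series()] with strictly positive values.
#' @return The log-transformed series, unit annotated as `log(<unit>)`.
#' @export
log_series <- function(s) {
  stopifnot(inherits(s, "annual_series"))
  bad <- which(s$values <= 0)
  if (length(bad) > 0L)
    stop(sprintf("nonpositive value (%g) at year %d; cannot take log",
                 s$values[bad[1]], years(s)[bad[1]]), call. = FALSE)
  series_update(s, log(s$values), unit = paste0("log(", s$unit, ")"))
}

#' Difference an annual series
#'
#' @param s an [annual_series()].
#' @param order differencing order (>= 1).
#' @return Series of `length(s) - order` values starting `order` years later;
#'   first differences of a linear trend are constant.
#' @export
difference <- function(s, order = 1L) {
  stopifnot(inherits(s, "annual_series"))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (length(s$values) <= order)
    stop("series too short to difference ", order, " time(s)", call. = FALSE)
  series_update(s, diff(s$values, differences = order), shift = order,
                unit = paste0("diff", if (order > 1) order else "",
                              "(", s$unit, ")"))
}

# MacKinnon (1994) response-surface approximation to the asymptotic p-value
# of the ADF tau statistic, constant-only regression, single series. The
# quadratic applies below tau_star, the cubic above; outside [tau_min,
# tau_max] the p-value is pinned to 0/1.
adf_pvalue <- function(stat) {
  tau_star <- -1.61; tau_min <- -18.83; tau_max <- 2.74
  if (stat <= tau_min) return(0)
  if (stat >= tau_max) return(1)
  if (stat <= tau_star)
    stats::pnorm(2.1659 + 1.4412 * stat + 0.038269 * stat^2)
  else
    stats::pnorm(1.7339 + 0.93202 * stat - 0.12745 * stat^2 -
                   0.010368 * stat^3)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against level stationarity. The regression
#' includes a constant but no trend (the series handed to it are logs or
#' differences, not trending levels by assumption); the number of augmenting
#' lags is chosen by AIC over 0..`max_lags` on a common estimation sample,
#' then the chosen model is refitted on the longest sample it allows.
#' P-values use the MacKinnon (1994) response-surface approximation.
#'
#' @param s an [annual_series()] of length >= 15, not constant.
#' @param max_lags upper bound for lag selection; default
#'   `floor((n - 1)^(1/3))`.
#' @return List of class `adf_result`: `statistic`, `p_value`, `n_lags_used`,
#'   `stationary_at_05` (`p_value < 0.05`).
#' @export
adf_test <- function(s, max_lags = NULL) {
  stopifnot(inherits(s, "annual_series"))
  y <- s$values
  n <- length(y)
  if (n < 15L) stop("ADF test needs at least 15 observations", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("ADF test undefined for a constant series", call. = FALSE)
  if (is.null(max_lags)) max_lags <- floor((n - 1)^(1/3))
  max_lags <- as.integer(max_lags)

  dy <- diff(y)
  ylag <- y[-n]
  # design over the common sample (drop first max_lags rows) so AICs compare
  build <- function(k, trim) {
    idx <- seq.int(trim + 1L, length(dy))
    X <- cbind(1, ylag[idx])
    if (k > 0L)
      for (j in seq_len(k)) X <- cbind(X, dy[idx - j])
    list(y = dy[idx], X = X)
  }
  aic_of <- function(k) {
    d <- build(k, max_lags)
    fit <- stats::lm.fit(d$X, d$y)
    nn <- length(d$y)
    nn * log(sum(fit$residuals^2) / nn) + 2 * ncol(d$X)
  }
  k_best <- which.min(vapply(0:max_lags, aic_of, numeric(1))) - 1L
  d <- build(k_best, k_best)
  fit <- stats::lm.fit(d$X, d$y)
  res <- fit$residuals
  dof <- length(d$y) - ncol(d$X)
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se
  p <- adf_pvalue(stat)
  structure(list(statistic = unname(stat), p_value = p,
                 n_lags_used = k_best, stationary_at_05 = p < 0.05),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF unit-root test: tau = %.3f, lags = %d, p = %.4f (%s at 5%%)\n",
              x$statistic, x$n_lags_used, x$p_value,
              if (x$stationary_at_05) "stationary" else "unit root not rejected"))
  invisible(x)
}

#' Direct age standardisation of mortality rates
#'
#' Weighted mean of age-specific rates under a fixed standard age structure
#' (e.g. the Segi world standard population), per year. Weights are
#' normalised to sum to one, so rescaling all weights by a positive constant
#' changes nothing. The historical registry rates used in practice arrive
#' already standardised; this operation exists for age-specific or synthetic
#' inputs.
#'
#' @param rates_by_age list of [annual_series()], one per age group, sharing a
#'   year range (they are aligned to the common range first).
#' @param standard_weights named numeric vector of positive weights keyed by
#'   `age_group`; must cover every supplied age group.
#' @param label,sex identity of the returned series.
#' @return An `annual_series` of standardised rates (`age_group = "all"`).
#' @export
age_standardise <- function(rates_by_age, standard_weights,
                            label = rates_by_age[[1]]$label,
                            sex = rates_by_age[[1]]$sex) {
  stopifnot(is.list(rates_by_age), length(rates_by_age) >= 1L)
  groups <- vapply(rates_by_age, `[[`, character(1), "age_group")
  missing <- setdiff(groups, names(standard_weights))
  if (length(missing) > 0L)
    stop("no standard weight for age group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  w <- as.numeric(standard_weights[groups])
  if (any(w < 0) || sum(w) <= 0)
    stop("standard weights must be nonnegative with positive sum", call. = FALSE)
  w <- w / sum(w)
  from <- max(vapply(rates_by_age, `[[`, integer(1), "start_year"))
  to <- min(vapply(rates_by_age, end_year, integer(1)))
  if (from > to) stop("age-specific series do not share a year range",
                      call. = FALSE)
  mats <- vapply(rates_by_age,
                 function(s) window_series(s, from, to)$values,
                 numeric(to - from + 1L))
  std <- as.numeric(if (is.matrix(mats)) mats %*% w else mats * w)
  annual_series(std, from, label = label, unit = rates_by_age[[1]]$unit,
                sex = sex, age_group = "all")
}
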