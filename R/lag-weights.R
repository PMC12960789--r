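#' Lag-weight profile
#'
#' Nonnegative weights over lags `0..max_lag` summing to one. Applied to a
#' consumption series these produce the lag-weighted exposure
#' `WA_t = sum_k w_k x_{t-k}` that enters the regression: the profile encodes
#' how many years of past drinking (or smoking) bear on this year's mortality.
#'
#' @param weights numeric vector of length `max_lag + 1`, weight for lag 0
#'   first; nonnegative, not all zero (normalised internally to sum to 1).
#' @param scheme provenance tag: `"ccf"`, `"geometric"`, `"point"` or
#'   `"uniform"`.
#' @return An object of class `lag_profile`.
#' @export
lag_profile <- function(weights, scheme = "ccf") {
  weights <- as.numeric(weights)
  if (length(weights) < 1L) stop("need at least the lag-0 weight", call. = FALSE)
  if (anyNA(weights) || any(weights < 0))
    stop("lag weights must be nonnegative", call. = FALSE)
  tot <- sum(weights)
  if (tot <= 0) stop("lag weights must not all be zero", call. = FALSE)
  structure(list(scheme = scheme, max_lag = length(weights) - 1L,
                 weights = weights / tot),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag_profile> scheme=%s, lags 0..%d\n", x$scheme, x$max_lag))
  print(round(stats::setNames(x$weights, paste0("lag", 0:x$max_lag)), 4))
  invisible(x)
}

#' @rdname lag_profile
#' @param k single lag receiving all the weight.
#' @export
point_mass_profile <- function(k) {
  k <- as.integer(k)
  if (k < 0) stop("lag must be >= 0", call. = FALSE)
  w <- rep(0, k + 1L); w[k + 1L] <- 1
  lag_profile(w, scheme = "point")
}

#' Geometric lag weights
#'
#' `w_k` proportional to `decay^k` for `k = 0..L`: the most recent years of
#' consumption get the largest weights, decaying geometrically with lag. Used
#' as the alternative lag structure in sensitivity analysis (typically with
#' L = 15 or 20).
#'
#' @param L maximum lag (years).
#' @param decay geometric ratio, strictly inside (0, 1).
#' @return A `lag_profile` with strictly decreasing weights summing to 1.
#' @examples
#' geometric_weights(1, 0.5)$weights  # 2/3, 1/3
#' @export
geometric_weights <- function(L, decay = 0.9) {
  L <- as.integer(L)
  if (L < 0) stop("L must be >= 0", call. = FALSE)
  if (!is.finite(decay) || decay <= 0 || decay >= 1)
    stop("decay must lie strictly inside (0, 1)", call. = FALSE)
  lag_profile(decay^(0:L), scheme = "geometric")
}

#' Pre-whiten an exposure/outcome pair for cross-correlation
#'
#' Shared trends and autocorrelation inflate raw cross-correlations, so both
#' series are first-differenced and then filtered with an autoregressive model
#' fitted to the differenced exposure (order chosen by AIC, at most
#' `ar_max`). The same filter is applied to both series, which preserves any
#' genuine lagged relation between them while flattening the exposure to
#' white noise.
#'
#' @param x exposure [annual_series()] (the series the AR filter is fitted to).
#' @param y outcome series, aligned with `x` first.
#' @param ar_max maximum AR order considered (default 5).
#' @return List with residual series `x`, `y` (equal length) and the selected
#'   `ar_order`.
#' @export
prewhiten <- function(x, y, ar_max = 5L) {
  al <- align(x, y)
  if (length(al[[1]]$values) < 30L)
    stop("pre-whitening needs at least 30 overlapping years", call. = FALSE)
  dx <- diff(al[[1]]$values)
  dy <- diff(al[[2]]$values)
  if (stats::sd(dx) == 0)
    stop("exposure is constant after differencing; cannot pre-whiten",
         call. = FALSE)
  arfit <- tryCatch(
    stats::ar(dx, aic = TRUE, order.max = ar_max, method = "yule-walker",
              demean = TRUE),
    error = function(e) stop("AR fit failed during pre-whitening: ",
                             conditionMessage(e), call. = FALSE))
  ord <- arfit$order
  whiten <- function(v) {
    if (ord == 0L) return(v)
    v <- v - mean(v)
    res <- v[(ord + 1L):length(v)]
    for (j in seq_len(ord))
      res <- res - arfit$ar[j] * v[(ord + 1L - j):(length(v) - j)]
    res
  }
  start <- al[[1]]$start_year + 1L + ord
  list(x = annual_series(whiten(dx), start, label = al[[1]]$label,
                         unit = "prewhitened", sex = al[[1]]$sex,
                         age_group = al[[1]]$age_group),
       y = annual_series(whiten(dy), start, label = al[[2]]$label,
                         unit = "prewhitened", sex = al[[2]]$sex,
                         age_group = al[[2]]$age_group),
       ar_order = ord)
}

#' Cross-correlation of pre-whitened residuals over nonnegative lags
#'
#' `ccf[k]` is the correlation of the exposure at time `t - k` with the
#' outcome at time `t`, for `k = 0..max_lag` (exposure leading outcome; the
#' direction of interest for a latency analysis). Correlations outside the
#' band `|2 / sqrt(n)|`, with `n` the number of overlapping pairs at lag 0,
#' are flagged significant.
#'
#' @param x_resid,y_resid equal-length residual series from [prewhiten()].
#' @param max_lag largest lag examined; must be below half the series length.
#' @return List of class `ccf_result`: `lags`, `ccf`, `critical_value`,
#'   `n_effective`, `significant_lags`.
#' @export
cross_correlate <- function(x_resid, y_resid, max_lag = 25L) {
  xv <- if (inherits(x_resid, "annual_series")) x_resid$values else as.numeric(x_resid)
  yv <- if (inherits(y_resid, "annual_series")) y_resid$values else as.numeric(y_resid)
  if (length(xv) != length(yv))
    stop("residual series must have equal length", call. = FALSE)
  n <- length(xv)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n / 2)
    stop("max_lag must be below half the series length", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero-variance input to cross-correlation", call. = FALSE)
  cc <- vapply(0:max_lag, function(k) {
    stats::cor(xv[seq_len(n - k)], yv[seq.int(k + 1L, n)])
  }, numeric(1))
  crit <- 2 / sqrt(n)
  structure(list(lags = 0:max_lag, ccf = cc, critical_value = crit,
                 n_effective = n,
                 significant_lags = (0:max_lag)[abs(cc) > crit]),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> n = %d, critical band = +/-%.3f\n",
              x$n_effective, x$critical_value))
  tab <- data.frame(lag = x$lags, ccf = round(x$ccf, 3),
                    significant = x$lags %in% x$significant_lags)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the lag length from a cross-correlation result
#'
#' Returns the largest lag whose correlation is positive and exceeds the
#' critical band, or 0 when none does. Only positive correlations count: a
#' rise in consumption is hypothesised to raise later mortality, so
#' significant negative lags are treated as noise for lag-length purposes.
#'
#' @param ccf a `ccf_result` from [cross_correlate()].
#' @return Integer lag length `L`.
#' @export
select_lag_length <- function(ccf) {
  stopifnot(inherits(ccf, "ccf_result"))
  pos <- ccf$lags[ccf$ccf > ccf$critical_value]
  if (length(pos) == 0L) 0L else max(pos)
}

#' Lag weights from the cross-correlation function
#'
#' Builds a weight profile over lags `0..L` from the estimated correlations:
#' weights are proportional to the positive, significant correlations
#' (everything else gets weight zero), normalised to sum to one. When no lag
#' is positive-significant the profile falls back to uniform weights over
#' `0..L`, so downstream code always receives a proper profile.
#'
#' @param ccf a `ccf_result`.
#' @param L profile length; at most `max(ccf$lags)`.
#' @return A `lag_profile` with `scheme = "ccf"` (or `"uniform"` on fallback).
#' @export
ccf_weights <- function(ccf, L = select_lag_length(ccf)) {
  stopifnot(inherits(ccf, "ccf_result"))
  L <- as.integer(L)
  if (L < 0) stop("L must be >= 0", call. = FALSE)
  if (L > max(ccf$lags)) stop("L exceeds the computed lag range", call. = FALSE)
  w <- rep(0, L + 1L)
  keep <- intersect(ccf$significant_lags[ccf$ccf[ccf$significant_lags + 1L] > 0],
                    0:L)
  if (length(keep) == 0L)
    return(lag_profile(rep(1, L + 1L), scheme = "uniform"))
  w[keep + 1L] <- ccf$ccf[keep + 1L]
  lag_profile(w, scheme = "ccf")
}

#' Apply a lag-weight profile to an exposure series
#'
#' Computes the lag-weighted exposure `WA_t = sum_k w_k x_{t-k}`. The output
#' starts `max_lag` years after the input (the first years cannot see far
#' enough back); because the weights sum to one, a constant series maps to
#' itself and a lag-0 point mass is the identity.
#'
#' @param x an [annual_series()] longer than `profile$max_lag`.
#' @param profile a [lag_profile()].
#' @return The weighted `annual_series`, label suffixed with `"_lagged"`.
#' @export
apply_weights <- function(x, profile) {
  stopifnot(inherits(x, "annual_series"), inherits(profile, "lag_profile"))
  L <- profile$max_lag
  if (length(x$values) <= L)
    stop("series must be longer than the profile's max lag (", L, ")",
         call. = FALSE)
  wa <- as.numeric(stats::filter(x$values, profile$weights,
                                 method = "convolution", sides = 1))
  wa <- wa[(L + 1L):length(wa)]
  annual_series(wa, x$start_year + L,
                label = if (L > 0) paste0(x$label, "_lagged") else x$label,
                unit = x$unit, sex = x$sex, age_group = x$age_group)
}
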