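#' ARIMA error specification
#'
#' Order of the error process for the differenced semi-log regression. The
#' differencing order is fixed at 1 for every study model — the regression is
#' always estimated on year-to-year changes — so only `p` and `q` vary
#' between strata (the dominant order in practice is (0,1,1), with (1,1,1)
#' and (1,1,3) appearing for liver strata).
#'
#' @param p autoregressive order (>= 0).
#' @param q moving-average order (>= 0).
#' @return An object of class `arima_spec` with fields `p`, `d` (always 1),
#'   `q`.
#' @export
arima_spec <- function(p = 0L, q = 1L) {
  p <- as.integer(p); q <- as.integer(q)
  if (p < 0 || q < 0) stop("ARMA orders must be >= 0", call. = FALSE)
  structure(list(p = p, d = 1L, q = q), class = "arima_spec")
}

#' Fit the differenced semi-log regression with ARIMA errors
#'
#' Estimates the study's core model
#' \deqn{\Delta \ln M_t = \alpha + \beta \Delta WA_t + \sum_i \mu_i \Delta C_{i,t} + \Delta E_t}
#' by exact maximum likelihood: the log-mortality outcome and all exposures
#' are first-differenced, then the linear regression with ARMA(p,q)
#' disturbances is fitted via [stats::arima()] in its state-space
#' representation (`method = "ML"`, deterministic initialisation, so refits
#' are bit-identical). The intercept of the differenced regression is the
#' drift \eqn{\alpha}. `beta_hat` is the coefficient of the first (primary)
#' exposure — one unit of exposure changes log mortality by \eqn{\beta}, i.e.
#' mortality by \eqn{(e^\beta - 1) \times 100} percent.
#'
#' @param outcome_log log mortality [annual_series()] (see [log_series()]).
#' @param exposures named list of [annual_series()], already lag-weighted;
#'   the first (or the one named by `primary`) is the exposure of interest.
#' @param spec an [arima_spec()]; default ARIMA(0,1,1).
#' @param primary name of the primary exposure coefficient; default
#'   `names(exposures)[1]`.
#' @param stratum optional list (`label`, `sex`, `age_group`) recorded on the
#'   fit for reporting.
#' @return Object of class `arimax_fit`: `spec`, `alpha_hat`, `beta_hat`,
#'   `covar_coefs`, `se`, `ci95`, `p_values`, `q10_stat`, `q10_p`, `n_obs`,
#'   `r_squared`, `loglik`, `aic`, `residuals`.
#' @export
fit_arimax <- function(outcome_log, exposures, spec = arima_spec(0, 1),
                       primary = NULL, stratum = NULL) {
  stopifnot(inherits(outcome_log, "annual_series"), inherits(spec, "arima_spec"))
  if (inherits(exposures, "annual_series")) exposures <- list(exposures)
  stopifnot(is.list(exposures), length(exposures) >= 1L)
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- vapply(exposures, `[[`, character(1), "label")
  if (is.null(primary)) primary <- names(exposures)[1]
  if (!primary %in% names(exposures))
    stop("primary exposure '", primary, "' not among the exposures", call. = FALSE)
  # put the primary exposure first under the canonical coefficient name
  exposures <- c(exposures[primary], exposures[setdiff(names(exposures), primary)])
  names(exposures)[1] <- "alcohol"

  # common year range of outcome and all exposures
  from <- max(outcome_log$start_year,
              vapply(exposures, `[[`, integer(1), "start_year"))
  to <- min(end_year(outcome_log),
            min(vapply(exposures, end_year, integer(1))))
  if (to - from + 1L < 25L)
    stop("need at least 25 overlapping years to fit (have ",
         max(0L, to - from + 1L), ")", call. = FALSE)
  y <- window_series(outcome_log, from, to)$values
  X <- vapply(exposures, function(s) window_series(s, from, to)$values,
              numeric(to - from + 1L))
  dy <- diff(y)
  dX <- apply(X, 2, diff)
  if (!is.matrix(dX)) dX <- matrix(dX, ncol = ncol(X),
                                   dimnames = list(NULL, colnames(X)))
  if (kappa(cbind(1, scale(dX, scale = FALSE)), exact = TRUE) > 1e8)
    stop("exposure design is (near-)collinear after differencing", call. = FALSE)

  if (spec$p == 0L && spec$q == 0L) {
    # with no ARMA terms the differenced regression is iid-Gaussian: OLS is
    # the exact ML estimator, and it tolerates a zero-residual perfect fit
    Xd <- cbind(intercept = 1, dX)
    ols <- stats::lm.fit(Xd, dy)
    cf <- ols$coefficients
    nn <- length(dy)
    sigma2 <- sum(ols$residuals^2) / nn  # ML variance, as stats::arima uses
    XtXinv <- chol2inv(chol(crossprod(Xd)))
    se <- stats::setNames(sqrt(pmax(sigma2 * diag(XtXinv), 0)), names(cf))
    res_fit <- ols$residuals
    ll <- sum(stats::dnorm(res_fit, 0, sqrt(max(sigma2, 1e-300)), log = TRUE))
    fit <- list(coef = cf, residuals = res_fit, loglik = ll,
                aic = -2 * ll + 2 * (length(cf) + 1))
  } else {
    fit <- tryCatch(
      stats::arima(dy, order = c(spec$p, 0L, spec$q), xreg = dX,
                   include.mean = TRUE, method = "ML"),
      error = function(e) stop("ARIMAX estimation failed: ",
                               conditionMessage(e), call. = FALSE))
    cf <- fit$coef
    se <- sqrt(pmax(diag(fit$var.coef), 0))
  }
  reg_names <- c("intercept", colnames(dX))
  keep <- reg_names[reg_names %in% names(cf)]
  z <- cf[keep] / se[keep]
  pv <- 2 * stats::pnorm(-abs(z))
  ci <- lapply(keep, function(nm)
    cf[nm] + c(-1, 1) * stats::qnorm(0.975) * se[nm])
  names(ci) <- keep
  names(ci)[names(ci) == "intercept"] <- "alpha"
  pv_named <- stats::setNames(as.numeric(pv), keep)
  names(pv_named)[names(pv_named) == "intercept"] <- "alpha"
  se_named <- stats::setNames(as.numeric(se[keep]), keep)
  names(se_named)[names(se_named) == "intercept"] <- "alpha"

  res <- as.numeric(fit$residuals)
  q10 <- if (stats::sd(res) > 0)
    stats::Box.test(res, lag = 10, type = "Ljung-Box",
                    fitdf = spec$p + spec$q)
  else list(statistic = c(Q = 0), p.value = 1)  # exact fit: nothing left to test
  r2 <- 1 - sum(res^2) / sum((dy - mean(dy))^2)
  covar <- setdiff(colnames(dX), "alcohol")
  ll <- if (inherits(fit, "Arima")) as.numeric(stats::logLik(fit)) else fit$loglik
  aic <- if (inherits(fit, "Arima")) stats::AIC(fit) else fit$aic

  structure(list(
    spec = spec,
    alpha_hat = unname(cf["intercept"]),
    beta_hat = unname(cf["alcohol"]),
    covar_coefs = stats::setNames(as.numeric(cf[covar]), covar),
    se = se_named, ci95 = ci, p_values = pv_named,
    q10_stat = unname(q10$statistic), q10_p = unname(q10$p.value),
    n_obs = length(dy), r_squared = r2,
    loglik = ll, aic = aic,
    residuals = res, stratum = stratum,
    years = c(from + 1L, to)
  ), class = "arimax_fit")
}

#' @export
print.arimax_fit <- function(x, ...) {
  cat(sprintf("ARIMAX(%d,1,%d) fit on %d differenced observations (%d-%d)\n",
              x$spec$p, x$spec$q, x$n_obs, x$years[1], x$years[2]))
  coefs <- c(alpha = x$alpha_hat, alcohol = x$beta_hat, x$covar_coefs)
  for (nm in names(coefs)) {
    ci <- x$ci95[[nm]]
    cat(sprintf("  %-10s %8.4f  95%% CI (%.4f, %.4f)  p = %.4f\n",
                nm, coefs[nm], ci[1], ci[2], x$p_values[nm]))
  }
  cat(sprintf("  Q(10) = %.2f (p = %.3f), R2 = %.3f\n",
              x$q10_stat, x$q10_p, x$r_squared))
  invisible(x)
}

#' Per-litre percentage effect
#'
#' In the semi-log model a coefficient \eqn{\beta} on per-capita consumption
#' means a one-litre change multiplies the mortality rate by \eqn{e^\beta} —
#' a \eqn{(e^\beta - 1) \times 100} percent change. `percent_effect` is the
#' bare transform; [effect_transform()] applies it to a fitted coefficient
#' and its confidence interval (the transform is monotone, so the CI maps
#' endpoint-wise).
#'
#' @param beta coefficient(s) on the log scale.
#' @return Percentage change per unit exposure.
#' @examples
#' percent_effect(0.035)  # ~3.6
#' @export
percent_effect <- function(beta) (exp(beta) - 1) * 100

#' @rdname percent_effect
#' @param fit an `arimax_fit`.
#' @param coefficient coefficient name (default `"alcohol"`).
#' @return `effect_transform`: object of class `effect_estimate` with
#'   `percent_per_litre`, `ci95_percent`, `p_value`.
#' @export
effect_transform <- function(fit, coefficient = "alcohol") {
  stopifnot(inherits(fit, "arimax_fit"))
  coefs <- c(alpha = fit$alpha_hat, alcohol = fit$beta_hat, fit$covar_coefs)
  if (!coefficient %in% names(coefs))
    stop("unknown coefficient '", coefficient, "'", call. = FALSE)
  b <- coefs[[coefficient]]
  ci <- fit$ci95[[coefficient]]
  effect_estimate(percent_effect(b), percent_effect(ci),
                  fit$p_values[[coefficient]])
}

#' @rdname percent_effect
#' @param percent_per_litre percentage change per litre.
#' @param ci95_percent length-2 numeric, transformed CI endpoints.
#' @param p_value two-sided p-value carried over from the coefficient.
#' @export
effect_estimate <- function(percent_per_litre, ci95_percent = c(NA_real_, NA_real_),
                            p_value = NA_real_) {
  structure(list(percent_per_litre = as.numeric(percent_per_litre),
                 ci95_percent = as.numeric(ci95_percent),
                 p_value = as.numeric(p_value)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%.1f%% per litre (95%% CI %.1f, %.1f; p = %.3f)\n",
              x$percent_per_litre, x$ci95_percent[1], x$ci95_percent[2],
              x$p_value))
  invisible(x)
}

#' Ljung-Box portmanteau test at 10 lags
#'
#' Residual whiteness diagnostic used on every fitted model: the Q(10)
#' statistic tests the first ten residual autocorrelations jointly, with
#' degrees of freedom reduced by the number of estimated ARMA parameters.
#'
#' @param residuals numeric vector or [annual_series()] of residuals,
#'   length >= 30, not constant.
#' @param fitdf number of ARMA parameters estimated (p + q).
#' @return List with `statistic` and `p_value`.
#' @export
ljung_box_q10 <- function(residuals, fitdf = 0L) {
  v <- if (inherits(residuals, "annual_series")) residuals$values
       else as.numeric(residuals)
  if (length(v) < 30L)
    stop("Ljung-Box Q(10) needs at least 30 observations", call. = FALSE)
  if (stats::sd(v) == 0)
    stop("Ljung-Box test undefined for a constant series", call. = FALSE)
  bt <- stats::Box.test(v, lag = 10, type = "Ljung-Box", fitdf = fitdf)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value))
}
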