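#' Sex-specific average per-capita consumption
#'
#' Splits a whole-population average consumption (litres of pure ethanol per
#' capita aged 15+, averaged over the observation window) into sex-specific
#' averages from the male share of total consumption. Assuming equal male and
#' female population sizes, a share `s` of the total implies a male per-capita
#' average of `2 s` times the overall average and a female average of
#' `2 (1 - s)` times it; survey evidence puts the male share near 0.675, and
#' with an overall average of 9.35 L this yields the pair 12.6 / 6.1 L.
#'
#' @param aacp_total whole-population average annual consumption (L/capita).
#' @param male_share male share of total consumption, strictly inside (0, 1);
#'   default 0.675.
#' @param sex `"male"` or `"female"`.
#' @param sex_population_ratio male:female population ratio; default 1
#'   (equal sexes).
#' @return Sex-specific average consumption in litres per capita.
#' @examples
#' sex_specific_aacp(9.35, 0.675, "male")    # 12.62
#' sex_specific_aacp(9.35, 0.675, "female")  # 6.08
#' @export
sex_specific_aacp <- function(aacp_total, male_share = 0.675,
                              sex = c("male", "female"),
                              sex_population_ratio = 1) {
  sex <- match.arg(sex)
  if (!is.finite(aacp_total) || aacp_total <= 0)
    stop("aacp_total must be positive", call. = FALSE)
  if (!is.finite(male_share) || male_share <= 0 || male_share >= 1)
    stop("male_share must lie strictly inside (0, 1)", call. = FALSE)
  r <- sex_population_ratio
  if (!is.finite(r) || r <= 0)
    stop("sex_population_ratio must be positive", call. = FALSE)
  # total consumption = aacp_total * (N_m + N_f); each sex's per-capita
  # average divides its consumption share by its own population
  if (sex == "male") aacp_total * male_share * (1 + r) / r
  else aacp_total * (1 - male_share) * (1 + r)
}

#' Aggregate alcohol-attributable fraction
#'
#' Computes the share of deaths from a cause attributable to alcohol from
#' aggregate data: `AAF = AACP * E / AM`, where AACP is the average per-capita
#' consumption over the observation window, AM the average mortality rate,
#' and `E = (e^beta - 1) * 100 * AM` the mortality rate attributable to each
#' litre. AM cancels, so the fraction reduces to AACP times the per-litre
#' percentage effect; `average_mortality` is accepted to exercise the full
#' identity but never changes the result. The linear extrapolation is only
#' meaningful for small changes, so fractions outside [0, 100] are clamped
#' with a warning.
#'
#' @param aacp_sex sex-specific average consumption (L/capita), see
#'   [sex_specific_aacp()]; must be nonnegative.
#' @param effect an `effect_estimate` (see [effect_transform()]) or a bare
#'   per-litre percentage.
#' @param sex,outcome provenance tags recorded on the result.
#' @param average_mortality optional average mortality rate AM (> 0); routes
#'   the computation through the E intermediate.
#' @return Object of class `aaf_result`: `aaf_percent`, `sex`, `outcome`,
#'   `aacp_sex`, `effect_percent_per_litre`.
#' @examples
#' compute_aaf(12.6, 3.6)  # 45.4% of male UADT cancer deaths
#' @export
compute_aaf <- function(aacp_sex, effect, sex = "n/a", outcome = "",
                        average_mortality = NULL) {
  if (!is.finite(aacp_sex) || aacp_sex < 0)
    stop("aacp_sex must be nonnegative", call. = FALSE)
  pct <- if (inherits(effect, "effect_estimate")) effect$percent_per_litre
         else as.numeric(effect)
  if (!is.null(average_mortality)) {
    if (!is.finite(average_mortality) || average_mortality <= 0)
      stop("average_mortality must be positive", call. = FALSE)
    e_rate <- pct / 100 * average_mortality      # deaths per 100k per litre
    aaf <- aacp_sex * e_rate / average_mortality * 100
  } else {
    aaf <- aacp_sex * pct
  }
  if (aaf > 100) {
    warning("attributable fraction exceeds 100%; clamped (linear ",
            "approximation is only valid for small changes)", call. = FALSE)
    aaf <- 100
  }
  if (aaf < 0) {
    warning("negative attributable fraction clamped to 0", call. = FALSE)
    aaf <- 0
  }
  structure(list(aaf_percent = aaf, sex = sex, outcome = outcome,
                 aacp_sex = aacp_sex, effect_percent_per_litre = pct),
            class = "aaf_result")
}

#' @export
print.aaf_result <- function(x, ...) {
  cat(sprintf("AAF %s%s: %.1f%% (AACP %.1f L x %.1f%%/L)\n",
              x$outcome, if (x$sex == "n/a") "" else paste0(" [", x$sex, "]"),
              x$aaf_percent, x$aacp_sex, x$effect_percent_per_litre))
  invisible(x)
}
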