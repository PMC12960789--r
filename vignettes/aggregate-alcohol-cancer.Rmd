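---
title: "Aggregate time-series analysis of population drinking and cancer mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate time-series analysis of population drinking and cancer mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcomort)
```

## The problem and the model

Individual-level studies establish alcohol as a causal factor for cancers of
the upper aerodigestive tract (UADT), liver, colorectum and female breast.
Aggregate (ecological) time-series analysis asks the complementary,
policy-facing question: when *population-level* per-capita consumption
changes, how does cause-specific cancer mortality change years later? The
units of analysis are whole calendar years of a national series — litres of
pure ethanol per person aged 15+, kilograms of tobacco per capita, per-capita
health expenditure, and age-standardised mortality rates per 100,000.

`alcomort` implements that analysis chain as a differenced semi-log
regression with ARIMA errors:

$$\Delta \ln M_t = \alpha + \beta\, \Delta WA_t + \sum_i \mu_i\, \Delta C_{i,t} + \Delta E_t$$

where $M_t$ is the mortality rate, $WA_t = \sum_k w_k x_{t-k}$ a lag-weighted
consumption series, $C_{i,t}$ the control series (tobacco, health
expenditure, themselves lag-weighted), and the error follows an ARMA process
on the differenced scale. The semi-log form reflects that chronic-disease
risk is convex in intake, and makes $\beta$ interpretable: one litre of
per-capita consumption multiplies the mortality rate by $e^\beta$, i.e.
changes it by $(e^\beta - 1)\times 100$ percent (`percent_effect()`).
Differencing removes the shared stochastic trends that otherwise produce
spurious correlation between slowly-moving national series; the Augmented
Dickey-Fuller test (`adf_test()`) checks that one round of differencing is
enough.

## Lag identification and weighting

Cancer mortality responds to drinking with a latency of up to two decades,
so the exposure must enter as a weighted history, not a contemporaneous
value. The package offers the two weighting families used in this
literature plus a diagnostic route to choose between them:

* **Cross-correlation weights** (`prewhiten()`, `cross_correlate()`,
  `ccf_weights()`). Both series are first-differenced, then filtered by an
  AR model fitted to the differenced exposure (order by AIC, at most 5) so
  that remaining cross-correlations are not inflated by the exposure's own
  autocorrelation. Correlations at lags $0..25$ outside the band
  $\pm 2/\sqrt{n}$ are significant; the lag length is the largest
  positive-significant lag, and the weights are the positive significant
  correlations themselves, normalised to sum to one. How estimated lag
  correlations become weights is genuinely underdetermined in this
  literature; clip-negative / keep-significant / normalise uses exactly the
  estimated quantities, always yields a proper profile, and degrades to
  uniform weights over $0..L$ when nothing is significant. A point-mass
  profile (all weight on one lag) is available as a third option.
* **Geometric weights** (`geometric_weights()`), $w_k \propto
  \text{decay}^k$ over a 15- or 20-year window — the sensitivity-analysis
  structure that favours recent consumption. The decay parameter is not
  pinned down by the applications this mirrors; the default 0.9 spreads
  non-negligible weight across the full window while still decreasing, and
  it is an explicit argument.

Only nonnegative lags (exposure leading outcome) are computed: mortality
cannot cause past drinking, and reverse-lag correlations would never enter a
weight profile anyway.

## Estimation choices

`fit_arimax()` differences the log outcome and all exposures explicitly and
fits the regression with ARMA$(p,q)$ disturbances by exact maximum
likelihood in state space (`stats::arima`, `method = "ML"`), so the
intercept of the differenced equation is the drift $\alpha$. This is the
only way to keep a drift term: `stats::arima` silently drops the constant
when asked to difference internally. When $p = q = 0$ the model is an iid
Gaussian regression, and the package fits it by ordinary least squares —
the exact ML estimator for that case, and one that tolerates the
zero-residual perfect-fit corner where the general optimiser's information
matrix is singular.

Defaults follow the dominant structure of these analyses: ARIMA(0,1,1)
errors, with other orders available per stratum. There is no automatic
order search — published coefficient tables come from fixed orders, and
reproducibility of a table demands a deterministic fit. Inference is
two-sided Wald with normal critical values. Model adequacy is summarised by
the Ljung-Box $Q(10)$ statistic on the residuals (degrees of freedom reduced
by $p+q$) and by $R^2$ computed on the differenced scale
($1 - SSE/SST$ of $\Delta\ln M$) — the only scale on which the model is
linear, and therefore the only one on which the statistic is comparable
across lag structures.

The ADF test is written in the package (constant, no trend, lag order by
AIC up to $\lfloor (n-1)^{1/3} \rfloor$), with p-values from the MacKinnon
(1994) response-surface approximation for the constant-only case. The
constant-only variant is appropriate because the test is applied to logged
or differenced series rather than trending levels, and the downstream model
fixes $d = 1$ regardless; the test is a diagnostic, not a model selector
here.

## Attributable fractions

With average per-capita consumption AACP over the observation window and
average mortality AM, the aggregate attributable fraction is
$\mathrm{AAF} = \mathrm{AACP}\cdot E / \mathrm{AM}$ with
$E = (e^\beta - 1)\times 100 \cdot \mathrm{AM}$ — AM cancels, so
`compute_aaf()` is the product of consumption and the per-litre percentage
effect (the AM route is implemented and tested as an algebraic identity).
Sex-specific AACP comes from the male share of total consumption (default
0.675 from national survey evidence): with equal sex population sizes, a
share $s$ gives male consumption $2s$ and female $2(1-s)$ times the overall
average (`sex_specific_aacp()`; the population ratio is an argument for
unequal sexes). The published 12.6 / 6.1 litre pair arises from an overall
average of 9.35 L under exactly this construction. AAFs are only computed
for coefficients significant at the two-sided 5% level, are linear
extrapolations valid for small changes, and are clamped to $[0, 100]$ with
a warning. Report output rounds the per-litre effect to one decimal before
the product, matching how such attribution tables are printed.

## The synthetic-data generator

Real historical registry data cannot ship with the package, so every stage
is validated against `simulate_study()`, which runs the model equation
*forwards* with known ground truth. Its defaults are the study conditions
the pipeline targets, chosen once:

* 109 years of exposure (a 1910–2018 record), mortality starting after the
  lag window, health expenditure starting 25 years late — so the differing
  record lengths of real registries are exercised;
* a smooth rise–plateau–decline exposure trend peaking mid-series (the
  gross shape of twentieth-century per-capita consumption) plus small AR(1)
  noise; alternatives: reflected random walk, constant;
* true per-litre effect $\beta = 0.035$ (the headline male UADT
  coefficient), tobacco coefficient $+0.05$, health coefficient $-0.02$
  (harmful and protective, magnitudes plausible for these units but not
  estimates of anything);
* a point mass at lag 20 as the true profile — the selected lag length in
  the motivating analyses;
* MA(1) disturbances ($\theta = 0.3$, innovation sd 0.005 on
  $\Delta\ln M$), so the well-specified fit is the default ARIMA(0,1,1);
* baseline mortality 10 per 100,000, drift $\alpha = 0$ so long-run
  movement comes only from the exposures.

Covariates are generated with independent seeds and act through the same
lag window as the exposure, which is also how the fitting pipeline enters
them.

What the generator deliberately does **not** emulate: age-structure
artefacts (series are generated per stratum, not standardised from
age-specific counts — `age_standardise()` is tested separately),
measurement revisions and unit conversions in historical sources,
epidemics or treatment breakthroughs that would appear as interventions,
and confounders moving with the exposure. Passing the recovery tests
therefore shows the estimator is correct *under the model*, not that the
model is correct for any country's history.

## What the test suite establishes

Problem sizes were chosen to give stable Monte Carlo rates while keeping
the default run short: 200 replicate studies for coefficient recovery
(CI coverage $\ge 90\%$, mean bias below 0.005), 100 replicates each for
lag identification (pre-whitened CCF peak at the true 20-year lag) and the
lung-cancer-style negative control (zero alcohol effect, nonzero tobacco
effect: alcohol non-significant and tobacco significant in $\ge 90\%$),
500 replicates for Ljung-Box size, 100 for ADF size and power, and exact
assertions for the worked per-litre-effect and AAF examples.

## Numerical and degenerate-input conventions

Internal missing values in a dataset are an error, never interpolated —
interpolation would fabricate the differences the model is fitted on;
series simply start and end where their records do. Constant series are
rejected by the ADF test, pre-whitening and the Ljung-Box test (all
undefined). Collinear exposure designs are refused by a condition-number
guard rather than silently dropped. Weight profiles are normalised at
construction to within $10^{-9}$. All fits are deterministic given their
inputs; repeated pipeline runs produce byte-identical reports.

## Known limitations

* The CCF route needs stochastic variation to find a lag: on short, smooth
  series it frequently finds no significant positive lag and falls back to
  uniform weights, attenuating the estimate. The point-mass and geometric
  schemes are the reliable choices when the lag is known a priori.
* Aggregate analysis cannot estimate alcohol-by-tobacco interaction, and no
  interaction term is offered.
* The AAF is the aggregate-data variant (consumption times per-litre
  effect), not the individual-level relative-risk formula; it inherits the
  linear-approximation caveat.
* Whole-population consumption is the only exposure; sex- and age-specific
  consumption series, where they exist, are outside the model.
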