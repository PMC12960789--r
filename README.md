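# alcomort

Aggregate time-series analysis of population drinking and cause-specific
cancer mortality.

## What this is for

Policy levers on alcohol — taxation, pricing, availability — act on whole
populations, so their evaluation needs the aggregate question: when annual
per-capita consumption (litres of pure ethanol, persons 15+) falls by one
litre, how much does mortality from alcohol-related cancers (upper
aerodigestive tract, liver, colorectum, female breast) fall years later?
`alcomort` implements the ecological analysis chain for that question, for
epidemiologists working with national annual series:

1. **Lag identification** — pre-whitened cross-correlation between
   differenced consumption and mortality series, with the ±2/√n significance
   band (`prewhiten()`, `cross_correlate()`, `select_lag_length()`);
2. **Lag-weighted exposure** — WAₜ = Σₖ wₖ xₜ₋ₖ with weights from the
   estimated cross-correlations, a geometric decay, or a point mass
   (`ccf_weights()`, `geometric_weights()`, `apply_weights()`);
3. **Differenced semi-log regression with ARIMA errors** —
   Δln Mₜ = α + β ΔWAₜ + Σᵢ μᵢ ΔCᵢ,ₜ + ΔEₜ, fitted by exact maximum
   likelihood, controlling for tobacco consumption and health expenditure
   (`fit_arimax()`);
4. **Per-litre effects** — (e^β − 1) × 100 percent change in the mortality
   rate per litre, with transformed confidence interval
   (`effect_transform()`);
5. **Attributable fractions** — AAF = AACP × per-litre effect, with the
   male/female split of total consumption (`sex_specific_aacp()`,
   `compute_aaf()`);
6. **Orchestration and sensitivity analyses** — per-stratum pipeline runs,
   geometric-lag and no-health-expenditure variants, and a lung-cancer-style
   negative control (`run_main_analysis()`, `run_sensitivity()`).

Historical registry data cannot ship with the package, so it includes a
synthetic-data generator (`simulate_study()`) that runs the model equation
forwards with known ground truth; every stage is validated against it.

## Worked example

Simulate a study-shaped dataset (109 years of exposure, a 20-year lag, MA(1)
noise, true per-litre log effect 0.035) and run the pipeline on one stratum:

```r
library(alcomort)

cfg <- sim_config(seed = 42)
sim <- simulate_study(cfg, strata = data.frame(label = "uadt", sex = "male",
                                               age_group = "all"))
pc <- pipeline_config(sim$dataset,
                      data.frame(label = "uadt", sex = "male",
                                 age_group = "all"),
                      lag_scheme = "point", point_lag = 20)
res <- run_main_analysis(pc)
res$fits[[1]]
#> ARIMAX(0,1,1) fit on 63 differenced observations (1956-2018)
#>   alpha        0.0003  95% CI (-0.0016, 0.0023)  p = 0.7303
#>   alcohol      0.0330  95% CI (0.0260, 0.0400)  p = 0.0000
#>   tobacco      0.0511  95% CI (0.0430, 0.0591)  p = 0.0000
#>   health      -0.0176  95% CI (-0.0232, -0.0121)  p = 0.0000
#>   Q(10) = 8.49 (p = 0.486), R2 = 0.860
res$effects[[1]]
#> 3.4% per litre (95% CI 2.6, 4.1; p = 0.000)
res$aafs[[1]]
#> AAF uadt [male]: 35.6% (AACP 10.6 L x 3.4%/L)
```

The estimated alcohol coefficient 0.033 recovers the generating value 0.035
inside its confidence interval; the per-litre effect says each litre of
per-capita consumption raises UADT mortality by about 3.4%, and with this
simulation's average male consumption of 10.6 L that makes roughly a third
of the simulated male UADT deaths alcohol-attributable. The tobacco (+)
and health-expenditure (−) controls are recovered with their generating
signs, and the Ljung-Box Q(10) finds no leftover residual autocorrelation.

A thin command-line front end over the same functions is installed at
`inst/cli/alcomort.R` (subcommands `simulate | adf | lags | fit | aaf | run |
sensitivity`).

## Vignette

`vignettes/aggregate-alcohol-cancer.Rmd` documents the model and its
assumptions, the lag-weighting schemes and their defaults, the estimation
and inference choices, what the synthetic generator does and does not
emulate, and known limitations.
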