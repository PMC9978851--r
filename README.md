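# phenofrass

Annual forest defoliation — cumulative frass deposition and total foliage
biomass loss in kg/ha — estimated from incomplete frass-trap field campaigns
and daily simulated larval phenology, for spring-feeding defoliators such as
the jack pine budworm (*Choristoneura pinus*) and the spongy moth
(*Lymantria dispar dispar*).

## Why

Frass traps measure defoliation well while they are deployed, but field
campaigns rarely span the whole feeding season: they start after feeding has
begun, stop before it ends, or sample one day per week. Summing the collected
frass then underestimates the annual total by an amount that depends on the
insect's feeding phenology that year. Weather-driven phenology simulators
supply the missing timing information — the daily percent of the population
in each larval instar — but say nothing about absolute density or mass.
`phenofrass` links the two data sources.

## The method

Two steps, for each species:

1. **Instar weighting.** Each feeding instar *i* gets a weight *wᵢ* (its
   share of total seasonal consumption) with *wᵢ* > 0 and Σ *wᵢ* = 1. The
   weighted-larvae signal WL(d) = Σᵢ wᵢ pᵢ(d) is proportional to the
   expected frass deposition rate; a free per-plot scale *sₚ* (estimated in
   closed form) converts it to kg·ha⁻¹·day⁻¹. Weights are optimized by
   simplex-constrained nonlinear least squares (softmax parameterization,
   multi-start BFGS) against observed plot-interval rates, and validated by
   leave-one-plot-out cross-validation (RMSE, nRMSE = RMSE/mean).
2. **CDF imputation.** With weights fixed, the season CDF
   F(d) = Σ_{d'≤d} WL(d') / Σ WL gives the fraction of seasonal consumption
   completed by day *d*. An observed cumulative *O* collected over a
   sampled mass fraction F_obs yields the annual total *O*/F_obs; every
   unsampled gap receives annual × (its F-mass). Leave-one-interval-out
   ("K-week") cross-validation scores the imputation.

Frass and foliage loss are parallel channels: foliage loss = frass/(1 − AD)
+ greenfall, where AD is the approximate digestibility (0.30 for *C. pinus*,
0.35 for *L. dispar dispar*).

A synthetic-data generator (`simulate_phenology()`, `simulate_frass()`,
`simulate_study()`) produces phenology tables and interval-censored trap
records with exactly the structure the method assumes, so every stage is
testable without field data and parameter recovery is measurable.

## Worked example

```r
library(phenofrass)

study <- simulate_study("cpinus", n_plots = 5, seed = 42)  # 10% trap noise
rates <- plot_interval_rates(study$records)
fit <- optimize_weights(rates, study$phenology, study$config)
fit
#> <instar_fit> Choristoneura pinus - frass channel, mode 'direct'
#>     L2     L3     L4     L5     L6     L7
#> 0.0122 0.0032 0.0290 0.0980 0.7296 0.1280
#>   objective RMSE: 0.5613 kg/ha/day over 35 intervals in 5 plots
#>   converged: TRUE (best of 8 starts)
```

The recovered weights show the expected negative skew — consumption peaks at
the second-to-last instar (L6 here) — and sit close to the simulation truth
(the species' field-calibrated weights). The objective is the pooled RMSE
between fitted and observed deposition rates.

```r
annual <- estimate_annual(rates, study$phenology, fit, study$config)
annual_report(annual)
#> # A tibble: 1 × 6
#>   species              year channel     n mean_annual sd_annual
#>   <chr>               <int> <chr>   <int>       <dbl>     <dbl>
#> 1 Choristoneura pinus  2006 frass       5        490.      138.

glance(kweek_crossval(rates, study$phenology, fit, study$config))
#> # A tibble: 1 × 6
#>   method channel  rmse  nrmse n_folds n_obs
#>   <chr>  <chr>   <dbl>  <dbl>   <int> <int>
#> 1 kweek  frass    6.52 0.0941      35    35
```

Mean annual frass of ~490 kg/ha across the five plots (observed plus
imputed head/tail gaps), with a K-week cross-validation nRMSE of 0.094:
withheld weekly collections are predicted from the season CDF to within
about 9% of their mean. `autoplot()` on an `impute_annual()` result draws
the observed interval bars, the CDF scaled to the annual total, and the
shaded unsampled gaps; `tidy()`/`glance()` return the tables above as
tibbles.

The shipped `calibrated_weights()` dataset carries field-calibrated weights
for both reference species; `weight_shares()` converts any weight set to
percent shares (e.g. L5 + L6 of *L. dispar dispar* jointly carry 83.4% of
seasonal consumption).

A command-line pipeline wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/phenofrass", package = "phenofrass"))')" \
  pipeline --out-dir run1 --seed 4 --species cpinus
```

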