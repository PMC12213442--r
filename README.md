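# clutchcurve

Within-clutch egg investment analysis with hierarchical generalized
additive mixed models (GAMMs).

## The problem

Do female birds allocate volume strategically along the laying sequence —
increasing it to protect late-hatching chicks (brood survival),
decreasing it (brood reduction), or favouring middle eggs? Much of the
classical literature compressed the whole sequence into the last-egg
deviation statistic

```
D = 100 * (v_last - mean(v)) / mean(v)   [% of clutch mean volume]
```

which is blind to hump-shaped patterns: a strategy spanning several
percent of mean volume can leave every clutch's |D| below 1%.
`clutchcurve` is for avian ecologists who want the full-sequence
alternative: egg volume (from the morphometric formula
`v = 0.4673·L·B² + 0.042` mm³, constants configurable per species)
modelled over the within-clutch standard-scored laying position with

- cubic regression spline main effects of position, clutch size, and the
  mean daily minimum temperature over the 3 days before laying (the
  egg-formation window),
- isotropic thin plate spline interaction surfaces between scaled
  covariates,
- random intercepts for clutch identity and year,
- a two-pass AR(1) residual structure: the lag-1 parameter is estimated
  by pooling consecutive within-clutch residual pairs from a first fit,
  then fixed in a block AR(1) working covariance (restarting at each
  clutch) for the final fit,

plus the surrounding diagnostics: Wald-like smooth tests, drop-one /
add-one deviance partitioning, concurvity, basis-dimension checks, and a
per-clutch ACF/PACF analysis of residual investment dependence with the
white-noise band `±2/sqrt(mean clutch size)`.

A configurable synthetic-data generator mirrors the model (clutch and
year intercepts, a quadratic hump-shaped order effect on the
within-clutch score scale, temperature effects, within-clutch AR(1)
residuals, geometry back-solved from volume), so the whole pipeline is
testable without field data and parameter recovery can be demonstrated
end to end.

## Worked example

```r
library(clutchcurve)

cfg <- run_config(mode = "simulate", seed = 7)   # default study conditions
run <- run_full_analysis(cfg, out_dir = "run7")
print(run)
#> clutchcurve full-analysis run
#>   1119 eggs / 145 clutches; mean volume 1513.48 mm^3 (clutch-mean CV 7.99%)
#>   pass-1 rho 0.037 (t = 1.17, df = 972); deviance explained 94.8%
#>   order-effect curve: -3.42% to 1.62% of mean volume
```

What the numbers mean: the simulated study (5 years, 145 clutches,
clutch sizes 4–10 around mean 7.68) carries a between-clutch CV of 7.69%
in egg volume, and the recovered clutch-mean CV (7.99%) and grand mean
(1513 vs 1506.24 mm³ configured) reflect that. The order-effect curve is
the partial effect of laying position with other covariates held at
their means — the generator's hump (−2.5% at early positions, +2% past
the middle, 0 at the end, relative to the grand mean) appears here
centred on its dataset mean, hence the −3.4%..+1.6% range. The pass-1
lag-1 correlation of *model residuals* sits near zero even though the
generating AR(1) ρ is 0.19: with clutch intercepts absorbing
within-clutch means of short series, residual centring removes almost
all lag-1 signal (see the methods vignette for why this matters when
interpreting field estimates).

Artifacts written to `run7/`: `terms.csv` (edf, statistic, p per smooth),
`partition.csv`, `concurvity.csv`, `basis_check.csv`, `lags.csv` and
`lag_summary.csv` (the per-clutch ACF/PACF table and its per-lag
mean ± sd summary with band flags), `clutches.csv` (including each
clutch's D statistic and first/late classification), 
`order_effect_curve.csv` (mm³ and % axes), `eggs.csv`,
`temperature.csv`, and `run.json` (seed, per-pass ρ, deviance
accounting).

Individual stages are ordinary functions if you want them à la carte:
`generate_dataset()`, `add_egg_geometry()`, `build_model_frame()`,
`two_pass_ar_fit()`, `test_smooth()`, `deviance_partition()`,
`predict_order_effect()`, `residual_lag_coefs()`,
`aggregate_lag_stats()`, `last_egg_deviation()`. Real data enter through
`load_egg_table()` / `load_temperature_table()`, which accept a column
map so externally named CSV deposits need no editing. A thin CLI lives
at `inst/scripts/clutchcurve` (`simulate`, `fit`, `report`).

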