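---
title: "Modelling within-clutch egg investment with hierarchical GAMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within-clutch egg investment with hierarchical GAMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Female birds may adjust the volume of successive eggs within a clutch —
increasing it along the laying order (a *brood survival* strategy,
equalising the prospects of late-hatching chicks), decreasing it (*brood
reduction*), or following a hump-shaped mixed pattern. Classical analyses
compressed this sequence into a single number, most prominently the
last-egg deviation statistic
\[
D = 100 \cdot \frac{v_{\text{last}} - \bar v}{\bar v},
\]
the percent deviation of the final egg's volume from the clutch mean.
`clutchcurve` implements a full-sequence alternative: a hierarchical
generalized additive mixed model (GAMM) of egg volume over the laying
order, with the supporting machinery (morphometric formulas, scaled model
frames, temperature windows, residual-dependence diagnostics) and a
synthetic-data generator that makes every stage testable without field
data.

## The model

Egg volume is derived from length $L$ and breadth $B$ (mm) by the
great-tit-calibrated formula $v = 0.4673\,L B^2 + 0.042$ (mm³); both
constants are configurable for other species. Sphericity is $B/L$. The
response (volume, or alternatively width, length or sphericity) is
standard-scored over the whole dataset. Laying position is standard-scored
*within* each clutch (`position_z`), so clutches of different sizes share
one functional scale; clutch size and the mean daily minimum temperature
over the three days before laying (the egg-formation window; the laying
day itself is excluded) are standard-scored over the dataset.

The default design is

\[
\text{volume}_{sc} \sim s(z) + s(\text{cs}) + s(T) +
  s(z, \text{cs}) + s(T, \text{cs}) +
  (1|\text{clutch}) + (1|\text{year}),
\]

with cubic regression spline main effects, *isotropic* thin plate spline
interaction surfaces (all interacting covariates share the
standard-deviation unit, so an isotropic basis is appropriate), and
random intercepts as penalized identity-penalty ("re") terms. Smoothing
parameters are chosen by restricted maximum likelihood; the Gaussian
response uses an identity link. An order-by-temperature surface and a
per-clutch factor smooth of position (the random-slope analogue) are
available but off by default — the latter mirrors the diagnostic-driven
choice to analyse the main model without per-female slopes.

Basis dimensions default to $k = 5$ for position (at most 10 distinct
positions), $k = 5$ for clutch size (7 distinct values), $k = 8$ for
temperature and a cap of $k = 25$ for the bivariate surfaces; every $k$
is clipped to the number of unique covariate values at fit time, and
`basis_check()` reports edf/k usage and the residual-pattern k-index so
the sufficiency of these choices is checked rather than assumed.

### Temporal autocorrelation: the two-pass AR(1) procedure

Laying is a time series — one egg per day — so residuals of consecutive
eggs within a clutch may be dependent. `two_pass_ar_fit()` first fits the
model with independent residuals, then estimates the lag-1 parameter by
pooling all consecutive within-clutch residual pairs across clutches
(pairs spanning different clutches are excluded) and taking their Pearson
correlation, with $t = r\sqrt{df}/\sqrt{1-r^2}$, $df = n_{\text{pairs}} -
2$. The second pass refits with that $\rho$ fixed in a block AR(1)
working covariance that restarts at each clutch's first egg. Internally
the AR(1) step is an exact innovations whitening of the response and
model bases ($e_1 = r_1$, $e_t = (r_t - \rho r_{t-1})/\sqrt{1-\rho^2}$
within each clutch) followed by REML fitting — i.e. generalized least
squares under the block AR(1) covariance. Partial models used for
deviance partitioning reuse the full model's $\rho$ so that all partial
fits share one residual covariance.

### Diagnostics and reporting

* `test_smooth()` — the Wald-like test of each smooth against a flat
  function, at reference rank close to the term's edf.
* `deviance_partition()` — drop-one and add-one explained-deviance
  shares. A main effect and an interaction surface containing the same
  covariate can trade deviance between them, so the `groups` argument
  partitions related terms as a unit (e.g. all laying-order terms
  together); grouped shares are the interpretable quantity.
* `concurvity_report()` — observed and worst-case concurvity of each
  term against the rest, plus the pairwise observed matrix. With
  isotropic interaction surfaces that contain main-effect directions,
  moderate observed concurvity between a main effect and "all other
  terms" is structural, which is why the pairwise matrix is reported.
  One practical consequence for the deviance partition: clutches
  experience distinct temperature windows, so when the clutch random
  intercept is dropped, the temperature smooth and interaction surfaces
  absorb part of the between-clutch variance; the drop-one share of
  clutch identity therefore understates the generative intraclass
  correlation by several points (about 9 under the default generator),
  which is the expected behaviour of drop-one accounting under
  concurvity, not an estimation defect.
* `predict_order_effect()` — the Figure-style partial-effect curve of
  laying order, holding other covariates at their scaled means and random
  intercepts at zero, reported in mm³ and as percent deviation from the
  dataset mean volume (the two axes are linked exactly by that mean).
* `residual_lag_coefs()` / `aggregate_lag_stats()` — per-clutch ACF and
  PACF of raw and AR-standardized residuals with the white-noise band
  $\pm 2/\sqrt{\bar n}$ ($\bar n$ = mean clutch size), per-lag mean ± sd
  across clutches, and the two significance flags (mean within band;
  mean ± sd interval overlapping zero). Clutch series are short, so the
  per-lag aggregation across clutches, not any single series, carries the
  inference.

PACF note: the lag-$\ell$ PACF is computed from the sample ACF by the
Durbin–Levinson recursion (`method = "yule_walker"`, the convention of
`pacf()`), which makes the lag-1 PACF identical to the lag-1 ACF. An
explicit least-squares autoregression variant (`method = "ols"`) is also
provided; at clutch-series lengths the two differ at the sequence edges,
and each is tested against its own independent oracle. Per-clutch ACF at
lag $\ell$ uses only clutches with at least $\ell + 2$ eggs; series are
centred on their own mean by default (global centring is a flag, since
either convention is defensible for residual series).

## The synthetic-data generator

`generate_dataset()` mirrors the fitted model. For each year, clutches
start on a random date in a laying window and lay one egg per day; the
volume of the egg at within-clutch score $z$ is

\[
v = \mu\,(1 + b_{\text{year}} + b_{\text{clutch}} + f(z) +
    \beta_T \tilde T + \gamma z \tilde T) + \varepsilon,
\]

where $f$ is the quadratic through three configurable anchor points,
$\tilde T$ is the dataset-scaled formation-window temperature, and
$\varepsilon$ is a within-clutch AR(1) process with stationary sd
`residual_sd`·$\mu$ that restarts independently at each clutch (the first
egg draws from the stationary distribution, keeping the marginal variance
constant across positions). Length and breadth are then back-solved from
volume under a sphericity profile increasing along the sequence, so the
geometry formulas are exercised end to end; the generator's latent
effects are all retained in a truth record for recovery tests.

Default conditions (each chosen once, as the study conditions the
generator emulates):

* 5 years × 29 clutches (~145 clutches, ~1100 eggs); grand mean volume
  1506.24 mm³; between-clutch CV 7.69% — the observed female-identity
  signal this analysis is designed around.
* Clutch sizes 4–10 with probabilities from a discretised normal with
  mean 7.68 and sd 0.67 (the observed clutch-size distribution).
* Order-effect anchors $f(-1.4) = -2.5\%$, $f(0.25) = +2\%$,
  $f(1.4) = 0$ — the hump-shaped pattern: first eggs slightly small, a
  peak just past mid-sequence, last eggs near the mean.
* AR(1) $\rho = 0.19$; residual sd 2% of the mean. The within-clutch
  residual sd net of the order effect is not an observable of the study
  this emulates; 2% is a deliberate, configurable choice that keeps the
  order effect (±2.5%) comparable to egg-level noise.
* Between-year sd 1% of the mean (interannual differences limited);
  season start day-of-year 91 with a 45-day window of first-egg dates
  (so both "first" and "late" clutches occur under the 30-day
  classification rule); daily minimum temperature 7 °C + 0.12 °C/day
  with noise sd 1.5 °C, a Mediterranean early-spring profile that also
  induces the laying-date/temperature collinearity the screen is meant
  to catch; sphericity profile $0.755 + 0.012 z$.

### What the generator does and does not emulate

It reproduces the variance structure the model assumes: a dominant
clutch-identity component, a shared hump-shaped order effect on the
within-clutch score scale, optional temperature main effects and
order-by-temperature modulation, and short-range within-clutch
dependence. It does **not** emulate per-female deviations from the shared
order-effect shape (random slopes), heteroskedasticity, measurement
error in calipers, skipped laying days, or seasonal changes in the order
effect. Two consequences matter for interpreting green tests. First,
parameter-recovery results certify the estimation machinery under the
assumed structure, not the adequacy of that structure for any real
population. Second, with a dominant clutch intercept and a short series
per clutch, the model's residuals are nearly within-clutch-centred draws
of $\varepsilon$; centring a short AR(1) series almost entirely removes
its lag-1 correlation, so the pass-1 pooled estimate recovered from
*model residuals* sits near zero even when the generating $\rho$ is 0.19
(the truth-record innovations do carry $\rho$, and the recovery test on
them is the meaningful generator check). A field estimate of 0.19 from
model residuals therefore implies within-clutch structure beyond this
generator — for example per-female trends, consistent with the sign flip
of the estimate when random slopes enter the model.

### The identifiable order-effect curve

The partial-effect curve is identifiable only up to the model intercept:
what `predict_order_effect()` shows is $f(z) - \bar f$, the order effect
centred on its egg-weighted dataset mean, expressed relative to the
dataset mean volume. Under the default anchors $\bar f \approx +0.49\%$,
and observed `position_z` extends to about $\pm 1.46$ (the extreme
positions of 9–10-egg clutches), where the default quadratic reaches
$-2.8\%$: a perfectly recovered curve therefore reads roughly $-3.3\%$
to $+1.5\%$ rather than the raw anchor values $-2.5\%$/$+2\%$. Recovery
tests compare the fitted curve with the mean-aligned true quadratic for
this reason.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations everywhere, making
  positions (1,2,3) → scores (−1, 0, 1) exact; every scaling is
  invertible from the stored scaling record, exactly.
* The pooled lag-1 estimator requires ≥ 3 pairs; |r| = 1 is flagged as
  degenerate rather than given an infinite t silently.
* Constant residual series are skipped in the per-clutch lag analysis;
  lags supported by fewer than two clutches are dropped with a warning.
* Random-intercept terms are dropped automatically when their factor has
  fewer than two levels (single-year simulations).
* Smooth k values are clipped to unique covariate counts; zero-edf terms
  report p = 1 with a flag.
* The 30-day first/late clutch boundary is inclusive; D uses the mean of
  all eggs including the last by default, with `exclude_last = TRUE` for
  the other literature convention (the original definition is ambiguous,
  so both are implemented and the default documented).
* The collinearity screen's default |r| threshold is 0.7 (configurable);
  laying date is computed and screened but excluded from the default
  design.
* Missing formation-window days are an error unless single-day linear
  interpolation is explicitly enabled.

## Problem sizes used in the tests

The test suite runs the oracle checks at full precision (1e-10), the
generator checks at study scale (~145 clutches), recovery of $\rho$ and
of the order curve over 20 seeded replicates, smooth-test calibration
over 500 null simulations of ~500 eggs, and power over 30 replicates at
~1100 eggs; `scripts/acceptance.R` re-runs the full default analysis at
study scale from a single seed. These sizes were chosen so each check is
statistically informative while the whole suite stays comfortably
runnable on a laptop.

## Known limitations

* Exact numerical replication of any specific external GAM
  implementation is not promised; correctness is established against
  closed-form oracles, simple-model equivalences (OLS, one-way ANOVA)
  and parameter recovery.
* The AR(1) working covariance is the only residual dependence structure
  offered (no ARMA extensions), matching the one-egg-per-day design.
* The per-clutch factor smooth is available but its diagnostics are the
  user's responsibility; it is off by default.
* Smooth-term p-values are approximate in the usual penalized-regression
  sense; the calibration test pins their type-I error near nominal under
  the null generator, not under arbitrary designs.
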