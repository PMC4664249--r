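---
title: "Identifying regional heat waves under missing monitor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying regional heat waves under missing monitor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epidemiological studies of extreme heat need exposure series that are
complete in time and representative in space. Weather-monitor records are
neither: daily maximum heat index is missing for some monitor-days, more
often outside the core summer months and much more often for some monitors
than others, mostly because of recording-frequency decisions rather than
instrument failure. Ignoring the gaps biases the percentile thresholds on
which heat-wave definitions rest, and therefore the heat waves themselves.

`hotspell` implements a complete pipeline for a warm-season (April 1 -
September 30, 183 days per year, February never intrudes) record from a
network of monitors grouped into forecast regions:

1. heat index from temperature and relative humidity,
2. three imputation models for missing daily maxima (plus the
   ignore-missing baseline),
3. warm-season percentile thresholds per monitor and per region,
4. a two-condition regional heat-wave definition with a benchmark upper
   threshold, and
5. a day-stratified hold-out comparison of the imputation methods by root
   mean squared prediction error (RMSPE).

A synthetic-data module generates ground-truth grids with the statistical
structure the models assume, so every stage can be tested end to end with a
known answer.

## Heat index

`heat_index_f()` follows the National Weather Service procedure: the simple
Steadman-average formula is evaluated first, and once it reaches 80 F the
full Rothfusz regression replaces it, with the published low-humidity
(RH < 13%, 80-112 F) and high-humidity (RH > 85%, 80-87 F) corrections. All
internal computation is in Fahrenheit; Celsius appears only in report
columns, rounded to two decimals.

## The data model

`hi_grid` is a monitors-by-days matrix of daily maximum heat index over a
`warm_calendar`. Three time coordinates matter and are kept distinct: the
running day index `t` (1..183 x years, in-season days only), the calendar
year, and the Julian day of year. Distances between monitors are
great-circle (haversine, Earth radius 6371 km).

## Imputation models

### Temporal: additive latent Gaussian model

Per monitor,
$$y_t = \mu + f_1(t) + f_2(\mathrm{year}_t) + f_3(\mathrm{day}_t) +
\varepsilon_t,\qquad \varepsilon_t \sim N(0,\sigma^2),$$
with $f_1$ a stationary AR(1) over the day index (short-range persistence
and long-range drift), $f_2$ a second-order random walk (RW2) over year
(one knot per year), and $f_3$ an RW2 over day-of-season 1..183 shared
across years (the seasonal shape). All three have sparse precision
matrices; the joint posterior precision is factored with a sparse Cholesky
decomposition, hyperparameters (AR coefficient, three component precisions,
noise variance) are estimated by maximizing the marginal likelihood with
the latent field integrated out (Nelder-Mead on log/tanh-transformed
parameters), and imputation uses the posterior mean. Design choices worth
noting:

* The intrinsic RW2 components get soft sum-to-zero constraints
  (pseudo-observations with precision $10^6$), and their log-generalized
  determinants use the rank-deficient form $(n-2)\log\tau + c$.
* The year component is dropped — mirroring how a year effect can be
  unidentifiable in records without between-year contrast — when only one
  season is observed, when its estimated variance collapses below $10^{-8}$
  of the data variance (a boundary estimate), or when the fit fails with it
  included; the model is then refit without it and the monitor flagged
  `year_effect_dropped`.
* Fewer than 30 observed days is an error: the three components cannot be
  separated.

Because the posterior mean reverts to $\mu + f_3$ wherever the AR(1)
component has no nearby data, imputed values in long gaps shrink toward the
seasonal mean. This is the model's documented weakness for extremes, and
the hold-out experiment measures it directly (the mean signed error on
>100 F truth is negative).

### Spatial: per-day ordinary kriging

For each day, $y_i = \mu_t + e_i$ with an unknown constant mean and
exponential covariance $\sigma^2 e^{-d/\rho}$ between monitors. Parameters
are estimated by restricted maximum likelihood separately per day, with the
sill profiled analytically and the range found by one-dimensional search on
`log` range in [1, 10000] km; prediction is ordinary kriging (weights sum
to one). Numerical choices:

* The nugget defaults to zero and is exposed as a ratio of the sill
  (`nugget_ratio`) for data that need it.
* A tiny relative jitter ($10^{-10}\sigma^2$) on the covariance diagonal
  keeps near-constant covariance matrices (very long estimated ranges)
  solvable; duplicated coordinates remain an error.
* Single-day REML on a few dozen points is noisy: a range estimate that
  collapses onto the search boundary is treated the same as an optimizer
  failure, and the day reuses pooled parameters (median sill and range over
  successfully fitted days of the same calendar month). In the default
  synthetic study this affects roughly 10% of days.
* Days with fewer than two observed monitors cannot be kriged; each missing
  monitor receives its own all-years monthly mean of observed values. A
  `fit_spatial_day()` call on such a day raises a
  `hotspell_fallback_required` condition.
* A day whose observations are all equal gives a zero sill; predictions are
  then the constant.

### Spatio-temporal: lag model with spatially correlated errors

$$y_{i,t} = \beta_0 + \beta_1\, y_{i,t-1} + e_{i,t},$$
with exponential spatial covariance among the within-day errors and days
independent given the lag. Estimation alternates generalized least squares
for $(\beta_0,\beta_1)$ with profiled REML for (sill, range) on the GLS
residuals, to convergence (at most 5 alternations; the covariance
likelihood uses up to 600 evenly spaced days, after which the estimates no
longer move at this record length). Fitting uses monitor-days where the day
and its within-season predecessor are both observed.

Imputation processes each season forward in time: a missing cell is
$\beta_0 + \beta_1 \cdot \mathrm{lag}$ plus the simple-kriging
interpolation (known mean zero, since lag residuals are mean-zero by
construction) of that day's observed residuals. Lags use observed values
when present, otherwise the previous day's imputed value. The first day of
a season has no lag and falls back to the per-day ordinary-kriging
predictor (or monthly means below two observed monitors). Ordinary kriging
is used for the per-day model because its mean is unknown; simple kriging
is used for the lag residuals because their mean is known to be zero — the
distinction is deliberate.

All three imputers never alter observed cells and return grids with no
missing and no non-finite values.

## Thresholds and the heat-wave definition

Percentiles (80/90/95/97.5 by default) are computed per monitor on the
completed 183 x years record, with linear interpolation between closest
order statistics (the R type-7 convention; at n ~ 7000 the convention moves
thresholds by well under 0.1 F). The ignore-missing route instead averages
the recorded monitors of a region per day and takes percentiles of that
series.

A regional heat wave is a maximal run of consecutive in-season days on
which (1) every monitor in the region exceeds its own 80th warm-season
percentile on every day, and (2) every monitor exceeds a regional upper
threshold on at least three (not necessarily consecutive) days of the run.
"Exceeds" is strict (>): the convention is conservative and documented, as
ties are vanishingly rare on continuous data. Runs shorter than three days
are discarded; runs cannot cross seasons because off-season days do not
exist in the grid. Because condition (2) can only lose qualifying days when
a period shrinks, a maximal condition-(1) run that fails (2) has no
qualifying sub-period — so the finder only needs to test maximal runs, and
the test suite checks it against brute-force enumeration of all periods.
The ignore-missing variant applies the same logic to the regional-average
series, with missing days breaking runs. We read condition (1) as binding
for every monitor on every day of the period, and condition (2) as a
per-monitor count over the period's days — each monitor independently.

The regional benchmark is the highest upper threshold, on an integer
Fahrenheit candidate grid (default 95..120), that still yields at least one
heat wave in the evaluation window (default the record's last eight years).
The heat-wave count is non-increasing in the threshold — raising it never
creates a wave — so a descending linear scan is exact.

## Hold-out validation

`draw_holdout()` removes a fraction (default 10%) of *observed* cells,
stratified by day: within each day, `round(fraction x observed monitors)`
cells (round half to even) are sampled without replacement. All methods are
refit on the same reduced grid and scored at the same cells (a paired
comparison on one draw; seed sweeps give replicates). RMSPE is reported
overall, on cells whose *true* value exceeds 100 F (37.78 C) — selection is
on the truth, not the prediction — and per monitor, with best/worst flags
per monitor.

## The synthetic generator

`generate_truth()` builds
$$y_{i,t} = \bar\mu + A\cos\!\big(2\pi(\mathrm{doy}_t - 196)/365.25\big) +
\gamma\,\frac{\mathrm{year}_t - y_0}{10} + b_i + a_{i,t} + \epsilon_{i,t},$$
where the anomaly field $a$ follows a vector AR(1) across days with
innovations jointly Gaussian across monitors under covariance
$(1-\phi^2)\,\sigma^2 e^{-d/\rho}$, so the stationary marginal variance is
exactly `spatial_sill`; the chain restarts at its stationary distribution
each season (seasons are half a year apart). Missingness is applied
cell-independently with probability month-rate x monitor-multiplier
(capped at 0.95): missing completely at random within month-by-monitor
strata, which matches missingness driven by recording policy rather than
weather.

Default values were fixed once from Florida warm-season climatology, before
any end-to-end result was inspected, and define the study conditions:

| parameter | default | why |
|---|---|---|
| monitors, span | 43, 1973-2012 | the scale of the motivating network |
| bounding box | 24.5-31 N, 87.6-80 W | Florida-like extent |
| seasonal mean, amplitude | 84, 12 F | April ~81 F to mid-July ~96 F daily maxima |
| peak day-of-year | 196 | mid-July |
| year trend | 0.3 F/decade | modest warming |
| AR coefficient | 0.6 | day-to-day persistence of daily-max anomalies |
| sill, range | 16 F^2, 300 km | ~4 F anomaly sd, synoptic-scale correlation |
| nugget | 1 F^2 | instrument/micro-scale noise |
| monitor offsets sd | 1.5 F | siting differences |
| missingness warm/cool | 0.05 / 0.18 | cooler months gappier |
| monitor multipliers | lognormal, ~7% sparse recorders (x8) | a few monitors record sparsely |

What the generator does *not* emulate: bursty missingness (real recording
gaps come in runs, which hurts temporal interpolation far more than
independent gaps do — so the temporal model's hold-out performance here is
an upper bound on its real-data usefulness), instrument changes, monitor
relocation, urban heat islands, and coastal-breeze effects. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
qualitative method ordering, not real-data error magnitudes.

## Problem sizes used by the checks

The package's own test suite runs the hold-out comparison at the full
default scale (43 monitors x 40 seasons, 10% hold-out), parameter-recovery
simulations at 43 monitors x 500 replicate days (per-day spatial model) and
43 monitors x 10 seasons (lag model), and the end-to-end
determinism/anomaly-detection check at a reduced 12 monitors x 9 seasons —
the determinism and detection properties do not depend on scale, and the
reduced size keeps the suite quick to iterate.

## Known limitations

* The temporal model's hyperparameter search is a local optimizer from
  moment-based starting values; pathological series could end in a local
  mode. The constant-series and simulated-component tests guard the common
  cases.
* Per-day REML with ~40 observations estimates the range with large
  variance; the pooled-parameter fallback mitigates but does not remove
  this.
* The lag model's coefficient standard errors come from the GLS information
  matrix at the final covariance estimate and ignore covariance-parameter
  uncertainty.
* The hold-out comparison is a single paired draw per seed by design;
  sweep seeds for uncertainty on RMSPE differences.
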