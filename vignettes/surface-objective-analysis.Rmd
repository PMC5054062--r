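---
title: "Surface objective analysis of air quality: model, error statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface objective analysis of air quality: model, error statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqoi)
```

## The problem and the model

Surface monitoring networks measure air pollution accurately but only at
points; chemical-transport models cover the whole domain but carry
systematic and random errors.  Optimal interpolation (OI) combines the
two into an hourly analysis grid that is more accurate than either.  For
one pollutant at one hour,

$$x^a = x^f + \mathbf{K}\,(y^o - H x^f),$$

where $x^f$ is the forecast (first guess), $H$ bilinear interpolation to
the stations, and $\mathbf{K} = (HB)^T (H(HB)^T + R)^{-1}$ the gain that
minimizes the analysis error variance for prescribed background ($B$)
and observation ($R$) error covariances.  We model the background error
correlation as homogeneous, isotropic and exponential (first-order
autoregressive, FOAR): the station-space innovation matrix is

$$A_{k_1 k_2} = \sigma^f(k_1)\,\sigma^f(k_2)\,
  e^{-\,d(k_1,k_2)/L_c}, \qquad
  A_{kk} = \sigma^f(k)^2 + \sigma^o(k)^2,$$

and the cross-covariance from a grid cell to station $k$ uses the
homogeneous grid-side value $\sigma^f_{\mathrm{grid}}$ with the local
station-side $\sigma^f(k)$, exactly as written (no extra mixing rule for
the cross term).  $R$ is diagonal: observation errors, including
representativeness, are taken spatially uncorrelated.  $A$ is symmetric
positive definite and factorized once per analysis by Cholesky; the
weights $w = A^{-1} d$ are then spread onto the grid by the exponential
cross-covariance.  Distances are great-circle (haversine, Earth radius
6371 km) — the covariance model needs a metric and this is the natural
one for lat/lon station lists without a projection.

Assumptions worth keeping in mind: homogeneity and isotropy of the
background error correlation (inhomogeneous variants have not proven
better for this problem and are out of scope), diagonal $R$, unbiased
errors after the regional bias correction, and error statistics that are
stationary within a stratum (pollutant × UTC hour × season, or `"all"`
for small experiments).

## Error statistics

Two independent estimates of the error variances are produced and
blended.

**Innovation variogram.**  Per station we collect the
observation-minus-prediction (OmP) series over the stratum (stations
with fewer than 30 paired hours are dropped).  Every station pair
contributes the covariance of its OmP series at the pair's separation;
pair covariances are averaged in 20-km bins up to 500 km, bins with
fewer than 10 pairs are discarded, and
$c(d) = \sigma_f^2 e^{-d/L_c}$ is fitted by pair-count-weighted
nonlinear least squares, excluding the origin.  The spatially correlated
part (the sill $\sigma_f^2$) estimates the background error variance
$\sigma_B^2$; the spatially uncorrelated remainder at zero distance, the
nugget $\mathrm{varOmP}(0) - \sigma_f^2$, estimates the observation
error variance $\sigma_o^2$.  By construction sill + nugget =
varOmP(0) exactly.  A fit is rejected (flagged, with a reason) when the
sill or nugget is non-positive or the fitted length leaves [5, 500] km.

**Representativeness model.**  Independently,
$$\sigma_o^2 = \sigma_{\mathrm{instr}}^2
  \left(1 + \frac{n\,\Delta x}{4 L_{\mathrm{repr}}}\right),$$
with $n = 4$ (the effective-resolution multiplier; no tuning factor),
$\Delta x$ the grid resolution in km, and representativeness lengths of
10, 4 and 2 km for rural, suburban and urban stations.  At
$\Delta x = 10$ km the representativeness-to-instrument variance ratios
are 1, 2.5 and 5 — a class-mean of about 3.  Then
$\sigma_B^2 = \mathrm{varOmP} - \sigma_o^2$ per station (stations where
this is non-positive are flagged unusable for the stratum).

Both routes have weaknesses (the variogram needs a dense network; the
representativeness model needs a credible instrument error), so when
both are available their arithmetic mean is used, with the provenance
recorded (`HL86`, `S14`, `blended`, `prescribed`).  The arithmetic mean
is our choice; nothing deeper is claimed for it.

Correlation lengths estimated from innovation variograms come out too
long for surface pollutants, so the analysis uses prescribed values:
60 km for O3 and PM2.5, 40 km for PM10, 20 km for NO2, all configurable
within the 10–100 km range supported by the surface-assimilation
literature.  Default instrument errors: O3 5 ppbv, PM2.5 2 µg/m³, NO2
and PM10 7.5% of a configured typical concentration.

The gain is governed by $\lambda = \sigma_B^2/\sigma_o^2$:
$1/\sigma_a^2 = 1/\sigma_B^2 + 1/\sigma_o^2$, equivalently
$\sigma_a^2/\sigma_B^2 = 1/(1+\lambda)$, so $\lambda = 2$ cuts the
background error variance by 3 (RMSE by $\sqrt3 \approx 1.7$) and
$\lambda = 1$ by 2 ($\sqrt2 \approx 1.4$).  `error_stats` exposes
$\lambda$ directly rather than enforcing any particular reading of
observation-to-model error ratios.

## Quality control and bias correction

Three checks run in order; all thresholds are configurable defaults and
every flag is recorded (a record is rejected by any flag, but all flags
are reported):

1. **Range**: concentration outside [min, max] per pollutant (O3
   [0, 250] ppbv, NO2 [0, 200] ppbv, PM2.5 [0, 500] µg/m³, PM10
   [0, 1000] µg/m³).
2. **Jump**: absolute hour-to-hour change above a per-pollutant limit
   (50/60/100/200); never applied to the first record or across gaps.
3. **Background check**: $|O - P| > k\sqrt{\sigma_B^2 + \sigma_o^2}$
   with $k = 4$.

Strict inequality flags; equality passes.  QC never modifies values and
is idempotent.  The numeric defaults are plausible operating values, not
authoritative ones, and should be reviewed per network.

Forecast bias is corrected regionally: inside a user-supplied polygon
the mean in-region innovation $b$ (requiring at least 5 accepted
stations) is added to the forecast; outside, the correction decays as
$b\,e^{-d/\,\mathrm{decay}}$ with distance to the nearest boundary point
(boundary sampled at ≤ 5 km), keeping the field continuous and bounded
by $|b|$.  Where regions compete, the nearest region wins, so
corrections never double-add.  The default 100-km decay is a smoothness
choice.  Correction is applied to the forecast *before* innovations are
recomputed and assimilated — this keeps the analysis consistent with the
corrected first guess; the alternative (correcting the analysis after
the fact) is not offered.

## AQHI

The exact index is
$\mathrm{AQHI} = \frac{10}{10.4}\cdot 100\,[(e^{0.000871\,\mathrm{NO_2}}-1)
+ (e^{0.000537\,\mathrm{O_3}}-1) + (e^{0.000487\,\mathrm{PM_{2.5}}}-1)]$,
reported on 3-h trailing running means (a window with any missing hour
is missing).  The linearized form
$(0.871\,\mathrm{NO_2}+0.537\,\mathrm{O_3}+0.487\,\mathrm{PM_{2.5}})/10.4$
is a lower bound ($e^x - 1 \ge x$); over balanced mixtures in which each
pollutant contributes a third of the index, its relative error grows
monotonically with the level and reaches ≈ 1.7% at index 10.  The 2%
bound does *not* hold for single-pollutant extremes (one exponential
term alone reaching index 10 gives ≈ 5%), so the balanced-mixture domain
is the one we test.  Categories use nearest-integer rounding (half away
from zero) floored at 1: 1–3 Low, 4–6 Moderate, 7–10 High, > 10 Extreme.

Gridded AQHI is a *pseudo objective analysis*: the exact formula applied
cellwise to the three pollutant analyses, not an assimilation of AQHI
observations.  Its companion "residual" grid is defined here as
exact-minus-linear — the local size of the nonlinear term, an
interpretation documented as such.  The seasonal climatology reports the
percentage of valid hours with AQHI strictly above 3 per cell and season
(DJF/MAM/JJA/SON); frequencies under 1% are floored to 0 (effectively
unpolluted).

## Validation

Metrics: mean bias (mean of O − P), error standard deviation, and FC2
(fraction of pairs with $0.5 \le P/O \le 2$, inclusive, over pairs with
$O$ at least a floor of 1 concentration unit — ratios are meaningless
near zero).  Cross-validation splits *stations* (never records) into
analysis and holdout sets — 90/10 for densely observed pollutants, 75/25
for sparse ones — with three independent seeded replicates whose holdout
pairs are pooled per UTC hour before computing metrics, an unpaired
two-sided t-test on mean OmP vs OmA, and a two-sided F-test on their
variances (unpaired is our reading; the report records it).  Hours with
fewer than 10 pooled pairs are not tested.  Verification regions split
east/west at 90°W (exactly −90 counts East) and by country label.

## The synthetic generator

The generator produces exactly the statistical structure the OI and the
estimators assume — and only that: truth fields are Gaussian random
fields with exponential covariance (dense Cholesky construction, exact
up to ~5000 cells); forecasts add an independent correlated error field
of variance $\sigma_B^2$ and length $L_c^{bg}$ plus optional constant
in-region offsets; observations add white noise with the
representativeness-model variance for the station's land-use class.
Real data differ in ways the generator deliberately omits: non-Gaussian
concentration distributions (lognormal-ish, bounded at zero), temporally
correlated representativeness error, diurnal cycles, inhomogeneous error
variances, and network geometry far from uniform.  Passing tests
therefore demonstrate correctness of the machinery under its own
assumptions, not skill on real networks.

Default scene conditions: a 26 × 28 cell grid over ~280 km × 280 km
(cell spacing ≈ 10 km, matching the 10-km `dx_km` the representativeness
model uses), background error variance 25, background correlation length
60 km, truth variance 100 with 200-km correlation (a smooth synoptic
field), hourly fields, land-use mix 0.3/0.3/0.4.

## Numerical choices and problem sizes

* Cholesky failure triggers one diagonal jitter of
  $10^{-8}\,\mathrm{tr}(A)/n$, then a hard error naming the closest
  station pair.  Stations closer than 1 km are averaged into a
  pseudo-station first.
* Variogram fitting uses Levenberg–Marquardt with positivity bounds;
  start values are taken from the first bin.
* Grid I/O is a self-describing CSV raster (header lines carry
  pollutant, units, valid time, `dx_km` and the coordinate vectors);
  values round-trip exactly at full precision.
* Bilinear interpolation never extrapolates: stations outside the
  cell-center hull are dropped with a reason.
* Test problem sizes were chosen so the full suite exercises every
  estimator at statistically meaningful sample sizes while remaining
  quick: parameter recovery uses 200 stations × 500 hours on the 10-km
  grid (recovers sill/length/nugget within a few percent); holdout
  cross-validation uses 400 stations × 24 hours — at ≈ 14-km spacing the
  network is dense relative to the 60-km correlation length, which is
  what gives the per-hour F-test its power.  Density is a design choice
  of the experiment: with 150 stations the same test shows improvement
  every hour but significance in only a quarter of hours, which is the
  expected behavior of a sparse network, not a defect.

## Known limitations

Homogeneous isotropic correlations cannot represent coastal, urban or
orographic gradients; the AQHI linearization bound applies only to
balanced mixtures; QC thresholds are placeholders pending
network-specific values; the regional bias estimator assumes enough
in-region stations and a bias that is constant within the region; and
the generator's observation noise is white in time, which flatters the
variogram method relative to real representativeness error.
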