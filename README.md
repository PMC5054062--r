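# aqoi — multi-pollutant surface objective analysis and AQHI mapping

`aqoi` builds hourly surface air-quality analysis maps by optimal
interpolation (OI): it fuses station observations of O3, NO2, PM2.5 and
PM10 with a gridded model forecast (the "first guess"), and derives from
the pollutant analyses a gridded Air Quality Health Index (AQHI) with its
health-risk categories and seasonal exceedance climatology.  It is aimed
at air-quality analysts and exposure/health researchers who need full
spatial coverage rather than point measurements, together with the error
statistics, quality control and holdout validation that make such maps
defensible.

## The method

For one pollutant at one hour, with forecast grid `x_f`, station
observations `y_o`, and bilinear interpolation `H` to the stations, the
analysis is

    x_a = x_f + K (y_o − H x_f)

where the gain `K = (HB)ᵀ A⁻¹` uses a homogeneous, isotropic exponential
(first-order autoregressive) background error correlation:

    A[k1,k2] = σf(k1) σf(k2) exp(−d(k1,k2)/Lc),   A[k,k] = σf(k)² + σo(k)²
    (HB)ᵀ[(i,j),k] = σf_grid σf(k) exp(−d((i,j),k)/Lc)

`A` (the innovation matrix) is inverted once per analysis by Cholesky
factorization.  The error statistics feeding it are estimated two ways
and blended:

* **Innovation variogram** (Hollingsworth–Lönnberg): pair up stations,
  compute the covariance of observation-minus-prediction (OmP) series per
  pair, bin by distance, and fit `c(d) = σf² exp(−d/Lc)` excluding the
  origin.  The fitted sill estimates the background error variance σ_B²;
  the nugget `varOmP(0) − σf²` estimates the observation error variance
  σ_o² (instrument + representativeness).
* **Representativeness model**: `σ_o² = σ_instr² (1 + nΔx / (4 L_repr))`
  with `n = 4`, grid resolution Δx, and representativeness lengths
  `L_repr` of 10/4/2 km for rural/suburban/urban stations; then
  `σ_B² = varOmP − σ_o²`.

The ratio `λ = σ_B²/σ_o²` controls the attainable gain:
`σ_a²/σ_B² = 1/(1+λ)`, so λ = 2 cuts the background error variance by a
factor of 3 (RMSE by √3 ≈ 1.7).

Around the OI core the package provides three-stage observation QC
(range, hourly jump, background check), regional mean-bias correction of
the forecast with exponential decay outside each region, internal and
station-holdout cross-validation (bias, error std, FC2, t/F significance
tests pooled over three random splits), the exact and linearized AQHI

    AQHI = (10/10.4)·100·[(e^0.000871·NO2 − 1) + (e^0.000537·O3 − 1) + (e^0.000487·PM2.5 − 1)]
    AQHI ≈ (0.871·NO2 + 0.537·O3 + 0.487·PM2.5)/10.4

with categories Low 1–3, Moderate 4–6, High 7–10, Extreme > 10, and a
synthetic-scene generator (Gaussian random fields with exponential
covariance, land-use-dependent observation noise, regional model bias)
that reproduces exactly the statistical structure the OI assumes, so the
whole chain is testable against known truth.

## Worked example

Simulate a 48-hour scene on a ~280 km × 280 km 10-km grid with known
truth (background error variance 25 ppbv², correlation length 60 km,
instrument error variance 4), estimate the error statistics from the
innovations, and analyze the first hour:

```r
library(aqoi)
scene <- simulate_scene(n_stations = 150, n_hours = 48,
                        sigma_instr2 = 4, seed = 42)
omp  <- scene_omp_matrix(scene)
fit  <- fit_error_statistics(omp, scene$stations, "O3",
                             dx_km = 10, sigma_instr2 = 4)
print(fit$variogram)
#> <variogram_estimate> 17/25 bins used, varOmP(0)=38.29
#>   sill=23.47 lc=59.2 km nugget=14.82
print(fit$stats)
#> <error_stats> O3 [all] sigma_b2=22.55 lc=60 km lambda=1.47 source=blended

obs1 <- scene$obs[scene$obs$time == 1, ]
prod <- analyze(scene$forecasts[[1]], obs1, scene$stations, fit$stats,
                qc_config = qc_config())
internal_validation(prod)
#>   quantity  mean_bias      std fc2 n_pairs
#> 1      OmP  2.3715997 5.759700   1     150
#> 2      OmA -0.0174867 3.666376   1     150
```

The variogram recovers the generating statistics (sill 23.5 vs true 25,
Lc 59.2 km vs 60; the nugget 14.8 matches the station-mix mean
observation error variance ≈ 16).  The analysis removes the forecast
bias (2.37 → −0.02 ppbv) and shrinks the error standard deviation at the
stations from 5.76 to 3.67 ppbv; against the (known) truth field the
grid-wide error drops from 4.14 to 2.87 ppbv.  `four_panel_export(prod,
"out/")` writes the forecast/analysis/increment rasters plus the
observation table.  The AQHI layer:

```r
aqhi_exact(20, 40, 20)                 # 4.7185
aqhi_linear(20, 40, 20)                # 4.6769
aqhi_category(aqhi_exact(20, 40, 20))  # Moderate
```

A command-line front end over the same functions lives in
`inst/cli/aqoi.R` (`simulate | qc | fit-stats | analyze | aqhi |
climatology | validate`).

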