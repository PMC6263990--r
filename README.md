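# phenoyield

Pixel-scale crop yield estimation from sparse NDVI time series, for
agricultural remote-sensing analysts working with high-revisit optical
imagery (30 m pixels, nominal 2-day repeat) over irrigated districts.
The package covers the whole chain from irregular, cloud-gapped NDVI
observations to county-level production totals, and ships a synthetic
scene generator so every stage can be exercised and validated without
external imagery.

## The method

**Seasonal curve.** Each pixel's NDVI trajectory over a season is
modelled by a five-parameter asymmetric logistic curve

```
NDVI(t) = a + (b/k) · (1+n)^(−(k+1)/k) · n · (k+1)^((k+1)/k),
      n = exp[(t + d·ln k − c)/d]
```

with baseline `a`, amplitude `b`, peak time `c` (DOY), time scale `d`
(days) and asymmetry `k`. The normalisation makes the curve peak exactly
at `t = c` with value `a + b`. Parameters are estimated per pixel by
bounded least squares on whatever acquisitions survived cloud screening
(at least 8 observations spanning 60+ days are required).

**Phenological characteristics.** The fitted curve yields three
characteristic points in closed form: the left inflection (maximum
growth rate), the right inflection (maximum withering rate) and the
seasonal maximum, with their times `t_inf_1, t_inf_2, t_max` and NDVI
values `NDVI_inf_1, NDVI_inf_2, NDVI_max`. The inflection times are the
roots of `n² − k(k+3)n + k² = 0` mapped back to the time axis.

**Yield models.** Eight standard predictor layouts per crop combine
daily-reconstructed NDVI samples (every 5 or 10 days across the growth
period — DOY 120–260 for maize, 160–260 for sunflower — or only up to
DOY 210 for pre-harvest forecasting) with the phenological
characteristics and the shape parameters `d, k`. Each (crop, layout)
pair gets its own random-forest regression (`ntree = 500`,
`mtry = ⌊p/3⌋`, `nodesize = 1`) calibrated against yields measured at
individual pixels, then applied across the crop mask:
`Y(i,j) = F(x(i,j))`.

**Validation.** Pixel yields (t/ha) are aggregated to county production
(t) as `pixel area × Σ yields`, and compared with reference statistics
via RMSE, relative error `RE = mean(|P−S|/P) × 100%` (normalised by the
estimate; a switch selects the conventional form), `R²` and adjusted
`R²`. Models are ranked by multi-year mean RMSE, ties broken by RE.

## Worked example

```r
library(phenoyield)
library(dplyr)

scene <- simulate_scene(scene_config(grid_height = 64, grid_width = 64, seed = 42))
calib <- calibration_set(scene, points = c(maize = 10, sunflower = 10))

params <- fit_curves(filter(scene$observations, crop == "maize"))
spec   <- model_spec(5, "maize")          # NDVI every 10 days up to DOY 210
X      <- build_predictors(filter(params, converged), spec)
train  <- inner_join(X, calib[calib$crop == "maize", c("pixel_id", "yield")],
                     by = "pixel_id")
model  <- fit_yield_rf(train, spec)
glance(model)
#> # A tibble: 1 × 8
#>   crop  model_id     p n_train ntree  mtry train_r2 oob_r2
#> 1 maize        5    10      80   500     3    0.942  0.361

ymap <- predict_yield_map(model, X, scene$pixels)
est  <- aggregate_production(ymap, scene$pixels)
est
#>   county crop  n_pixels area_ha mean_yield production
#> 1      1 maize      383    34.5       11.2       385.
#> 2      2 maize      256    23.0       11.3       260.
#> 3      3 maize      448    40.3       11.3       454.
#> 4      4 maize      384    34.6       11.3       389.

val <- inner_join(est, scene$counties, by = c("county", "crop"),
                  suffix = c("_est", "_true"))
metrics(val$production_true, val$production_est, p = 1)
#>    rmse    re    r2 adj_r2     n     p
#> 1  8.47  2.09 1.000  1.000     4     1
```

The forest, trained on 80 calibration pixels, explains 94% of the
training-yield variance; applied wall-to-wall and summed per county it
recovers true county production within about 2% relative error on this
clean synthetic district (RMSE 8.5 t against productions of 260–450 t).

`plot_curve_fit()`, `plot_yield_map()` and the `autoplot()` methods
visualise fits, maps and predictor importance; `run_pipeline()` executes
the whole chain (simulate → fit → predictors → train → map → aggregate →
evaluate → rank) into a checksummed output directory, and
`inst/scripts/phenoyield-cli.R` exposes the same stages as shell
subcommands.

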