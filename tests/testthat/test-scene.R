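test_that("scenes are bit-identical under a seed and differ across seeds", {
  s1 <- small_scene(seed = 101)
  s2 <- small_scene(seed = 101)
  s3 <- small_scene(seed = 102)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$observations, s2$observations)
  expect_false(identical(s1$observations$ndvi, s3$observations$ndvi))
})

test_that("zero noise and zero dropout put every acquisition on the true curve", {
  sc <- simulate_scene(scene_config(grid_height = 16, grid_width = 16,
                                    seed = 5, cloud_dropout = 0,
                                    noise_sd = 0))
  counts <- dplyr::count(sc$observations, .data$pixel_id)
  expect_true(all(counts$n == 101))  # DOY 90..290 every 2 days
  joined <- dplyr::inner_join(sc$observations, sc$truth,
                              by = c("year", "pixel_id", "crop"))
  expected <- mapply(function(t, a, b, c, d, k) ndvi_curve(t, a, b, c, d, k),
                     joined$doy, joined$a, joined$b, joined$c, joined$d,
                     joined$k)
  expect_equal(joined$ndvi, expected, tolerance = 1e-12)
})

test_that("every crop pixel keeps at least 8 observations under heavy dropout", {
  sc <- simulate_scene(scene_config(grid_height = 24, grid_width = 24,
                                    seed = 9, cloud_dropout = 0.85))
  counts <- dplyr::count(sc$observations, .data$pixel_id)
  expect_gte(min(counts$n), 8)
  expect_error(
    simulate_scene(scene_config(grid_height = 16, grid_width = 16,
                                seed = 9, cloud_dropout = 0.995)),
    "cloud_dropout")
})

test_that("configuration and prior validation reject impossible settings", {
  expect_error(scene_config(crop_fractions = c(maize = 0.8, sunflower = 0.3,
                                               other = 0)), "sum")
  expect_error(scene_config(crop_fractions = c(maize = -0.1, sunflower = 0.3,
                                               other = 0)), "nonnegative")
  expect_error(scene_config(window = c(290, 90)), "increasing")
  expect_error(scene_config(revisit_days = 0), "revisit")
  expect_error(crop_priors("maize", d = c(5, 2)), "positive")
  expect_error(crop_priors("maize", k = c(-1, 2)), "positive")
})

test_that("county truth conserves pixel production exactly", {
  sc <- small_scene(seed = 77)
  total_truth <- sum(sc$counties$production)
  total_pixels <- sum(sc$truth$yield) * sc$config$pixel_area_ha
  expect_equal(total_truth, total_pixels, tolerance = 1e-12)
  # aggregation of the true-yield map reproduces the truth table
  ymap <- dplyr::left_join(sc$truth[sc$truth$year == 1, ],
                           sc$pixels[, c("pixel_id", "row", "col")],
                           by = "pixel_id")
  agg <- aggregate_production(ymap, sc$pixels, sc$config$pixel_area_ha)
  cmp <- dplyr::inner_join(agg, sc$counties,
                           by = c("county", "crop"),
                           suffix = c("_agg", "_truth"))
  expect_equal(nrow(cmp), nrow(sc$counties))
  expect_equal(cmp$production_agg, cmp$production_truth, tolerance = 1e-6)
})

test_that("simulated maize yields match the survey-statistics anchor", {
  sc <- simulate_scene(scene_config(grid_height = 80, grid_width = 80,
                                    seed = 11))
  y <- sc$truth$yield[sc$truth$crop == "maize"]
  expect_gte(length(y), 2000)
  expect_lt(abs(mean(y) - 11.515), 0.5)
  expect_lt(abs(sd(y) - 2.253), 0.6)
})

test_that("yields are deterministic functions of phenology when yield noise is zero", {
  pr <- list(crop_priors("maize", yield_noise_sd = 0))
  sc <- simulate_scene(scene_config(grid_height = 16, grid_width = 16,
                                    seed = 21,
                                    crop_fractions = c(maize = 0.8,
                                                       sunflower = 0,
                                                       other = 0)),
                       priors = pr)
  link <- pr[[1]]$yield_link
  ph <- extract_phenology(sc$truth)
  daily_sum <- vapply(seq_len(nrow(sc$truth)), function(i) {
    sum(ndvi_curve(120:260, sc$truth$a[i], sc$truth$b[i], sc$truth$c[i],
                   sc$truth$d[i], sc$truth$k[i]))
  }, numeric(1))
  expected <- link[["intercept"]] +
    link[["w_ndvi_max"]] * ph$ndvi_max +
    link[["w_season_length"]] * (ph$t_inf_2 - ph$t_inf_1) +
    link[["w_integral"]] * daily_sum
  expect_equal(sc$truth$yield, expected, tolerance = 1e-10)
})

test_that("the survey design produces clustered calibration records", {
  sc <- simulate_scene(scene_config(seed = 42))
  cs <- calibration_set(sc)
  expect_equal(sum(cs$crop == "maize"), 272)      # 34 points x 8 pixels
  expect_equal(sum(cs$crop == "sunflower"), 432)  # 54 points x 8 pixels
  expect_false(any(duplicated(cs$pixel_id)))
  # pixels of one sampling point are mutually contiguous (same field)
  spread <- cs |>
    dplyr::group_by(.data$crop, .data$sampling_point) |>
    dplyr::summarise(dr = diff(range(.data$row)),
                     dc = diff(range(.data$col)), .groups = "drop")
  expect_lte(max(spread$dr), sc$config$field_size)
  expect_lte(max(spread$dc), sc$config$field_size)

  one <- calibration_set(sc, points = c(maize = 1L), pixels_per_point = 1L)
  expect_equal(nrow(one), 1)
  expect_equal(one$yield,
               sc$truth$yield[sc$truth$pixel_id == one$pixel_id &
                              sc$truth$year == 1])
  expect_error(calibration_set(sc, points = c(maize = 10000L)), "eligible")
})

test_that("scene export and run-config round-trip through plain text", {
  sc <- simulate_scene(scene_config(grid_height = 16, grid_width = 16,
                                    seed = 3))
  dir <- withr::local_tempdir()
  files <- write_scene(sc, dir)
  expect_true(all(file.exists(files[c("pixels", "observations", "truth",
                                      "county_truth")])))
  obs <- read_observations(files[["observations"]])
  expect_equal(nrow(obs), nrow(sc$observations))
  expect_equal(obs$ndvi, sc$observations$ndvi, tolerance = 1e-12)

  cfgfile <- file.path(dir, "run.yaml")
  write_run_config(sc$config, sc$priors, cfgfile)
  back <- read_run_config(cfgfile)
  expect_equal(unclass(back$config), unclass(sc$config))
  expect_equal(lapply(unname(back$priors), unclass),
               lapply(unname(sc$priors), unclass))
})
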