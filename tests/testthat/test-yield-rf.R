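spec7 <- model_spec(7, "maize")

test_that("a constant response is predicted exactly", {
  df <- pheno_training_data(n = 60)
  df$yield <- 10.0
  # randomForest warns about the degenerate (constant) response; the
  # prediction contract is what matters here
  m <- suppressWarnings(fit_yield_rf(df, spec7))
  expect_equal(predict(m, df), rep(10.0, 60))
})

test_that("forests are deterministic under a seed and sensitive to it", {
  df <- pheno_training_data(n = 120)
  m1 <- fit_yield_rf(df, spec7, config = rf_config(seed = 11))
  m2 <- fit_yield_rf(df, spec7, config = rf_config(seed = 11))
  m3 <- fit_yield_rf(df, spec7, config = rf_config(seed = 12))
  expect_identical(predict(m1, df), predict(m2, df))
  expect_false(identical(predict(m1, df), predict(m3, df)))
})

test_that("prediction joins columns by name, not position", {
  df <- pheno_training_data(n = 100)
  m <- fit_yield_rf(df, spec7)
  shuffled <- df[, rev(names(df))]
  expect_identical(predict(m, df), predict(m, shuffled))
  expect_error(predict(m, df[, 1:3]), "lacks predictors")
})

test_that("mean-of-trees predictions stay inside the training response range", {
  df <- pheno_training_data(n = 120)
  m <- fit_yield_rf(df, spec7)
  wild <- pheno_training_data(n = 200, seed = 99)
  wild$N_max <- wild$N_max + 0.5  # extrapolation region
  p <- predict(m, wild)
  expect_gte(min(p), min(df$yield))
  expect_lte(max(p), max(df$yield))
})

test_that("duplicating every training row barely moves the fit", {
  df <- pheno_training_data(n = 272)
  m1 <- fit_yield_rf(df, spec7, config = rf_config(seed = 5))
  m2 <- fit_yield_rf(df[rep(seq_len(nrow(df)), 2), ], spec7,
                     config = rf_config(seed = 5))
  expect_lt(mean(abs(predict(m1, df) - predict(m2, df))), 0.1)
})

test_that("more trees do not hurt out-of-bag accuracy", {
  df <- pheno_training_data(n = 200)
  df$yield <- df$yield + rnorm(200, 0, 0.2)
  oob_mse <- function(ntree) {
    m <- fit_yield_rf(df, spec7, config = rf_config(ntree = ntree, seed = 3))
    m$forest$mse[ntree]
  }
  expect_lte(oob_mse(500), oob_mse(50) * 1.05)
})

test_that("training contracts are enforced", {
  df <- pheno_training_data(n = 40)
  expect_error(fit_yield_rf(df, spec7), "50 calibration")
  df2 <- pheno_training_data(n = 60)
  df2$N_max[3] <- NA
  expect_error(fit_yield_rf(df2, spec7), "missing values")
  expect_error(fit_yield_rf(dplyr::select(pheno_training_data(60), -"N_max"),
                            spec7), "missing columns")
})

test_that("yield maps cover the mask and leave other crops as no-data", {
  df <- pheno_training_data(n = 100)
  m <- fit_yield_rf(df, spec7)
  pixels <- tibble::tibble(pixel_id = 1:6, row = 1L, col = 1:6,
                           crop = c("maize", "maize", "sunflower",
                                    "other", "none", "maize"))
  X <- pheno_training_data(n = 3, seed = 2)[, spec7$predictors]
  X$pixel_id <- c(1L, 2L, 6L)
  map <- predict_yield_map(m, X, pixels)
  expect_equal(nrow(map), 6)
  expect_equal(is.na(map$yield), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))

  # zero crop pixels: an all-NA map, not an error
  no_crop <- dplyr::mutate(pixels, crop = "other")
  empty <- predict_yield_map(m, X, no_crop)
  expect_true(all(is.na(empty$yield)))
})

test_that("tidy and glance summarise the model", {
  df <- pheno_training_data(n = 100)
  m <- fit_yield_rf(df, spec7, config = rf_config(ntree = 100))
  td <- tidy(m)
  expect_equal(sort(td$term), sort(spec7$predictors))
  gl <- glance(m)
  expect_equal(gl$p, 6)
  expect_equal(gl$mtry, 2)
  expect_equal(gl$ntree, 100)
  expect_gt(gl$train_r2, 0.9)  # smooth deterministic response
})
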