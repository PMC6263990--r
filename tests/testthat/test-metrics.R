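test_that("identical series score perfectly", {
  m <- metrics(S = c(1, 2, 3), P = c(1, 2, 3), p = 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$re, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$adj_r2, 1)
})

test_that("relative error normalises by the estimate by default", {
  expect_equal(relative_error(S = 10, P = 8), 25)          # |8-10|/8
  expect_equal(relative_error(S = 10, P = 8,
                              denominator = "observed"), 20)
  m <- metrics(S = c(10, 20), P = c(8, 16), p = 1)
  expect_equal(m$re, 25)
  m_obs <- metrics(S = c(10, 20), P = c(8, 16), p = 1,
                   re_denominator = "observed")
  expect_equal(m_obs$re, 20)
})

test_that("adjusted R-squared applies the sample-size penalty", {
  expect_equal(adjusted_r2(0.5, n = 11, p = 1), 1 - 0.5 * 10 / 9)
  expect_equal(round(adjusted_r2(0.5, n = 11, p = 1), 4), 0.4444)
  # converges to r2 as n grows at fixed p
  for (n in c(1e2, 1e4, 1e6)) {
    gap <- abs(adjusted_r2(0.6, n, 3) - 0.6)
    expect_lt(gap, 0.4 * 4 / (n - 4))
  }
  expect_error(adjusted_r2(0.5, n = 4, p = 3))
})

test_that("R-squared is the squared correlation and symmetric in its arguments", {
  set.seed(31)
  for (i in 1:5) {
    S <- rnorm(40, 10, 2)
    P <- S + rnorm(40, 0, 1)
    m <- metrics(S, P, p = 1)
    # independent route: univariate regression R^2
    expect_equal(m$r2, summary(lm(P ~ S))$r.squared, tolerance = 1e-12)
    expect_equal(m$r2, metrics(P, S, p = 1)$r2, tolerance = 1e-12)
    expect_lte(m$adj_r2, m$r2)
    # RMSE invariant under common permutation
    ord <- sample(40)
    expect_equal(m$rmse, metrics(S[ord], P[ord], p = 1)$rmse)
  }
})

test_that("metric preconditions are enforced", {
  expect_error(metrics(1, 1, p = 1), "at least 2")
  expect_error(metrics(c(1, 2), c(0, 2), p = 1), "zero estimated")
  expect_error(metrics(c(1, 1), c(1, 2), p = 1), "zero variance")
  expect_error(metrics(c(1, 2, 3), c(1, 2), p = 1))
})

test_that("county aggregation is exact arithmetic with conservation", {
  pixels <- tibble::tibble(pixel_id = 1:100,
                           county = rep(1:2, each = 50))
  ymap <- tibble::tibble(pixel_id = 1:100, crop = "maize", yield = 10)
  one_county <- aggregate_production(ymap, dplyr::mutate(pixels, county = 1),
                                     pixel_area_ha = 0.09)
  expect_equal(one_county$production, 90)  # 100 px * 0.09 ha * 10 t/ha
  expect_equal(one_county$mean_yield, 10)

  split2 <- aggregate_production(ymap, pixels, pixel_area_ha = 0.09)
  expect_equal(sum(split2$production), one_county$production)

  # any partition refinement conserves the total
  fine <- dplyr::mutate(pixels, county = rep(1:10, each = 10))
  split10 <- aggregate_production(ymap, fine, pixel_area_ha = 0.09)
  expect_equal(sum(split10$production), 90)

  expect_error(
    aggregate_production(dplyr::mutate(ymap, pixel_id = pixel_id + 1000),
                         pixels), "absent")
})

test_that("models rank by mean RMSE with RE as tie-break", {
  tab <- tibble::tibble(
    model_id = c(2, 2, 5, 5, 8, 8), year = rep(1:2, 3),
    rmse = c(0.80, 0.80, 0.75, 0.75, 0.75, 0.75),
    re = c(7.0, 7.0, 6.1, 6.1, 7.0, 7.0))
  rk <- rank_models(tab)
  expect_equal(rk$model_id, c(5, 8, 2))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$mean_rmse[1], 0.75)
  expect_equal(rk$mean_re[1], 6.1)
  expect_error(rank_models(tab[0, ]), "empty")
})
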