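#' Yield-estimation error metrics
#'
#' Computes the four standard validation metrics between observed values
#' `S` (field-measured or official statistics) and model estimates `P`:
#'
#' \deqn{RMSE = \sqrt{\tfrac{1}{N}\sum_i (S_i - P_i)^2}}
#' \deqn{RE = \tfrac{1}{N}\sum_i |P_i - S_i| / P_i \times 100\%}
#' \deqn{R^2 = \mathrm{cor}(S, P)^2}
#' \deqn{\bar R^2 = 1 - (1 - R^2)\,\frac{N - 1}{N - p - 1}}
#'
#' Note the relative error normalises by the *estimate* `P_i` by default,
#' matching the printed definition this package follows; set
#' `re_denominator = "observed"` for the more conventional normalisation
#' by `S_i`. For validation regressions of estimated against statistical
#' values, use `p = 1` (univariate regression).
#'
#' @param S Observed values (length N >= 2).
#' @param P Estimated values (same length).
#' @param p Number of predictors of the model being assessed (for the
#'   adjusted R-squared penalty).
#' @param re_denominator `"estimated"` (default) or `"observed"`.
#' @return A one-row tibble: `rmse` (units of input), `re` (percent),
#'   `r2`, `adj_r2`, `n`, `p`.
#' @examples
#' metrics(S = c(10.2, 11.5, 9.8), P = c(10.0, 11.9, 10.1), p = 1)
#' @export
metrics <- function(S, P, p, re_denominator = c("estimated", "observed")) {
  re_denominator <- match.arg(re_denominator)
  stopifnot(is.numeric(S), is.numeric(P), length(S) == length(P),
            length(p) == 1L, p >= 0)
  N <- length(S)
  if (N < 2L) stop("need at least 2 paired values", call. = FALSE)
  if (anyNA(S) || anyNA(P)) stop("missing values in S or P", call. = FALSE)
  denom <- if (re_denominator == "estimated") P else S
  if (any(denom == 0)) {
    stop("relative error undefined: zero ", re_denominator, " value",
         call. = FALSE)
  }
  if (stats::sd(S) == 0 || stats::sd(P) == 0) {
    stop("R^2 undefined: zero variance in S or P", call. = FALSE)
  }
  rmse <- sqrt(mean((S - P)^2))
  re <- mean(abs(P - S) / abs(denom)) * 100
  r2 <- stats::cor(S, P)^2
  adj_r2 <- 1 - (1 - r2) * (N - 1) / (N - p - 1)
  tibble::tibble(rmse = rmse, re = re, r2 = r2, adj_r2 = adj_r2,
                 n = N, p = p)
}

#' Relative error between observed and estimated values
#'
#' Mean absolute relative deviation in percent. The default normalises
#' each pair by the estimate `P_i`.
#'
#' @param S Observed values.
#' @param P Estimated values (same length; no zeros under the default
#'   denominator).
#' @param denominator `"estimated"` (default) or `"observed"`.
#' @return Relative error in percent (length 1).
#' @examples
#' relative_error(S = 10, P = 8)  # |8 - 10| / 8 = 25%
#' @export
relative_error <- function(S, P, denominator = c("estimated", "observed")) {
  denominator <- match.arg(denominator)
  stopifnot(length(S) == length(P), length(S) >= 1L)
  den <- if (denominator == "estimated") P else S
  if (any(den == 0)) stop("zero denominator in relative error", call. = FALSE)
  mean(abs(P - S) / abs(den)) * 100
}

#' Adjusted R-squared
#'
#' Penalises the coefficient of determination for model size:
#' `1 - (1 - r2) (n - 1) / (n - p - 1)`.
#'
#' @param r2 Coefficient of determination.
#' @param n Sample size (must exceed `p + 1`).
#' @param p Number of predictors.
#' @return Adjusted R-squared (length 1).
#' @examples
#' adjusted_r2(0.5, n = 11, p = 1)
#' @export
adjusted_r2 <- function(r2, n, p) {
  stopifnot(n > p + 1)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Aggregate a pixel yield map to county production
#'
#' Sums per-pixel yields (t/ha) times pixel area (ha) over each
#' county-crop combination, the validation bridge from 30 m yield maps to
#' official county statistics. Mean yield is production divided by crop
#' area, so conservation holds exactly: summing county productions over
#' any partition returns the whole-map production.
#'
#' @param yield_map Tibble with `pixel_id, crop, yield` (NA yield =
#'   no-data; from [predict_yield_map()], or `scene$truth` renamed).
#' @param pixels Pixel table with `pixel_id, county` (e.g. `scene$pixels`).
#' @param pixel_area_ha Pixel area in hectares (default 0.09).
#' @return A tibble `county, crop, n_pixels, area_ha, mean_yield,
#'   production` (tonnes) with one row per county-crop present.
#' @export
aggregate_production <- function(yield_map, pixels, pixel_area_ha = 0.09) {
  stopifnot(all(c("pixel_id", "crop", "yield") %in% names(yield_map)),
            all(c("pixel_id", "county") %in% names(pixels)))
  if (!all(yield_map$pixel_id %in% pixels$pixel_id)) {
    stop("yield map contains pixels absent from the pixel table",
         call. = FALSE)
  }
  yield_map |>
    dplyr::filter(!is.na(.data$yield)) |>
    dplyr::left_join(pixels[, c("pixel_id", "county")], by = "pixel_id") |>
    dplyr::group_by(.data$county, .data$crop) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      area_ha = dplyr::n() * pixel_area_ha,
      mean_yield = mean(.data$yield),
      production = sum(.data$yield) * pixel_area_ha,
      .groups = "drop")
}

#' Rank competing yield models by multi-year accuracy
#'
#' Averages each model's RMSE and relative error over years and ranks
#' models by mean RMSE ascending, breaking ties by mean RE ascending.
#'
#' @param metric_table Tibble with columns `model_id`, `year`, `rmse`,
#'   `re` (one row per model-year; extra columns ignored).
#' @return A tibble `model_id, mean_rmse, mean_re, n_years, rank`,
#'   ordered best first.
#' @examples
#' rank_models(tibble::tibble(model_id = c(2, 2, 5, 5),
#'                            year = c(1, 2, 1, 2),
#'                            rmse = c(0.9, 0.8, 0.7, 0.8),
#'                            re = c(8, 7, 6, 6)))
#' @export
rank_models <- function(metric_table) {
  stopifnot(is.data.frame(metric_table),
            all(c("model_id", "rmse", "re") %in% names(metric_table)))
  if (nrow(metric_table) == 0L) stop("empty metric table", call. = FALSE)
  metric_table |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     mean_re = mean(.data$re),
                     n_years = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$mean_rmse, .data$mean_re) |>
    dplyr::mutate(rank = dplyr::row_number())
}
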