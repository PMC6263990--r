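#' Fit the asymmetric logistic curve to one NDVI series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) of the five-parameter seasonal curve against an
#' irregular series of (DOY, NDVI) observations. Starting values come
#' from data moments -- the parameterisation makes `c` the peak time and
#' `a + b` the peak value, so `a0 = min(ndvi)`, `b0 = max - min`,
#' `c0 = DOY of the maximum`, `d0 = span/6` are strong starts -- with a
#' small multi-start over the asymmetry (`k0` in 0.5, 1, 2); the best
#' converged restart by residual sum of squares is kept.
#'
#' Box constraints keep the solution physical: `a` in `[-0.5, 0.5]`,
#' `b` in `(0, 1.5]`, `c` within the observed window plus a 30-day margin,
#' `d` in `[2, 60]` days, `k` in `[0.05, 20]`.
#'
#' @param doy Observation days of year, strictly increasing, in `[1, 366]`.
#' @param ndvi NDVI values in `[-1, 1]`, same length as `doy`.
#' @param min_obs Minimum number of observations required (default 8,
#'   keeping the 5-parameter fit overdetermined on sparse series).
#' @param min_span Minimum DOY span required (default 60 days).
#' @return A one-row [curve_params()] tibble with `rss` and `converged`;
#'   on failure (degenerate series, no restart converged) `converged` is
#'   `FALSE` and the parameter columns are `NA`.
#' @examples
#' t <- seq(90, 290, by = 2)
#' fit_ndvi_curve(t, ndvi_curve(t, a = 0.12, b = 0.68, c = 221, d = 16, k = 1.3))
#' @export
fit_ndvi_curve <- function(doy, ndvi, min_obs = 8L, min_span = 60) {
  stopifnot(length(doy) == length(ndvi))
  if (is.unsorted(doy, strictly = TRUE)) {
    stop("doy must be strictly increasing", call. = FALSE)
  }
  if (any(doy < 1 | doy > 366)) stop("doy must lie in [1, 366]", call. = FALSE)
  if (any(ndvi < -1 | ndvi > 1)) stop("ndvi must lie in [-1, 1]", call. = FALSE)
  if (length(doy) < min_obs || diff(range(doy)) < min_span ||
      stats::sd(ndvi) < 1e-8) {
    return(failed_fit())
  }

  span <- diff(range(doy))
  start_base <- list(
    a = max(-0.5, min(0.5, min(ndvi))),
    b = max(1e-3, min(1.5, max(ndvi) - min(ndvi))),
    c = doy[which.max(ndvi)],
    d = max(2, min(60, span / 6))
  )
  lower <- c(a = -0.5, b = 1e-6, c = min(doy) - 30, d = 2, k = 0.05)
  upper <- c(a = 0.5, b = 1.5, c = max(doy) + 30, d = 60, k = 20)

  best <- NULL
  for (k0 in c(1, 0.5, 2)) {
    start <- c(start_base, list(k = k0))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ndvi ~ ndvi_curve(doy, a, b, c, d, k),
        data = data.frame(doy = doy, ndvi = ndvi),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(coef = stats::coef(fit), rss = rss)
      if (rss < 1e-10) break  # exact fit; no need for more restarts
    }
  }
  if (is.null(best)) return(failed_fit())
  co <- best$coef
  curve_params(co[["a"]], co[["b"]], co[["c"]], co[["d"]], co[["k"]],
               rss = best$rss, converged = TRUE)
}

failed_fit <- function() {
  out <- tibble::tibble(a = NA_real_, b = NA_real_, c = NA_real_,
                        d = NA_real_, k = NA_real_,
                        rss = NA_real_, converged = FALSE)
  class(out) <- c("curve_params", class(out))
  out
}

#' Batch-fit NDVI curves for every pixel in an observation table
#'
#' Applies [fit_ndvi_curve()] to each pixel's series in a long-format
#' observation table. Pixels whose fit fails are retained in the output
#' with `converged = FALSE` so callers can drop and log them; they are
#' never silently imputed.
#'
#' @param observations A data frame with columns `pixel_id`, `doy`,
#'   `ndvi` (extra columns such as `crop` are carried through, one value
#'   per pixel).
#' @param min_obs,min_span Passed to [fit_ndvi_curve()].
#' @return A tibble with one row per pixel: `pixel_id`, carried-through
#'   columns, `a, b, c, d, k, rss, converged`.
#' @export
fit_curves <- function(observations, min_obs = 8L, min_span = 60) {
  stopifnot(all(c("pixel_id", "doy", "ndvi") %in% names(observations)))
  carry <- intersect("crop", names(observations))
  observations |>
    dplyr::arrange(.data$pixel_id, .data$doy) |>
    dplyr::group_by(.data$pixel_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_ndvi_curve(df$doy, df$ndvi,
                            min_obs = min_obs, min_span = min_span)
      for (col in carry) fit[[col]] <- df[[col]][1]
      fit
    }) |>
    dplyr::ungroup()
}
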