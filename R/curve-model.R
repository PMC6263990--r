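#' Normalized Difference Vegetation Index
#'
#' Computes NDVI from red and near-infrared surface reflectance,
#' `(nir - red) / (nir + red)`. For 4-band CCD imagery of the kind this
#' package emulates, band 4 is the NIR band and band 3 the red band.
#'
#' @param red Red-band reflectance, in `[0, 1]`. Vectorised.
#' @param nir Near-infrared reflectance, in `[0, 1]`. Vectorised.
#' @return Numeric vector of NDVI values in `[-1, 1]`.
#' @examples
#' ndvi(red = 0.1, nir = 0.5)
#' @export
ndvi <- function(red, nir) {
  stopifnot(is.numeric(red), is.numeric(nir))
  if (any(red < 0 | red > 1 | nir < 0 | nir > 1, na.rm = TRUE)) {
    stop("reflectances must lie in [0, 1]", call. = FALSE)
  }
  denom <- nir + red
  if (any(denom == 0, na.rm = TRUE)) {
    stop("NDVI undefined where nir + red == 0", call. = FALSE)
  }
  (nir - red) / denom
}

#' Curve-parameter container
#'
#' Bundles the five parameters of the asymmetric logistic NDVI curve:
#' baseline `a` (NDVI units), amplitude `b` (> 0), peak time `c` (DOY),
#' time scale `d` (days, > 0) and asymmetry `k` (> 0, dimensionless;
#' `k = 1` gives a symmetric curve). The curve attains its maximum
#' `a + b` exactly at `t = c`.
#'
#' @param a,b,c,d,k Curve parameters (length-1 numerics).
#' @param rss Residual sum of squares of the fit, if any.
#' @param converged Logical convergence flag.
#' @return A one-row tibble of class `curve_params`.
#' @export
curve_params <- function(a, b, c, d, k, rss = NA_real_, converged = NA) {
  validate_curve_params(a, b, c, d, k)
  out <- tibble::tibble(a = a, b = b, c = c, d = d, k = k,
                        rss = rss, converged = converged)
  class(out) <- c("curve_params", class(out))
  out
}

validate_curve_params <- function(a, b, c, d, k) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(d), is.numeric(k))
  if (any(b <= 0)) stop("amplitude b must be > 0", call. = FALSE)
  if (any(d <= 0)) stop("time scale d must be > 0", call. = FALSE)
  if (any(k <= 0)) stop("asymmetry k must be > 0", call. = FALSE)
  if (any(a < -0.5 | a > 0.5)) {
    stop("baseline a must lie in [-0.5, 0.5]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate the asymmetric logistic NDVI curve
#'
#' The seasonal NDVI trajectory is modelled as
#' \deqn{f(t) = a + (b/k)\,(1+n)^{-(k+1)/k}\, n \,(k+1)^{(k+1)/k}, \quad
#'       n = \exp[(t + d \ln k - c)/d].}
#' The normalisation makes `f(c) = a + b` the unique interior maximum and
#' `f(t) -> a` in both tails. Evaluation is carried out in log space so the
#' tails do not overflow for large `|t - c| / d`.
#'
#' @param t Day of year (numeric vector).
#' @param a,b,c,d,k Curve parameters; see [curve_params()]. A one-row
#'   data frame with these columns may be passed as `a` instead.
#' @return NDVI values, same length as `t`.
#' @examples
#' ndvi_curve(200:240, a = 0.12, b = 0.68, c = 220, d = 15, k = 1)
#' @export
ndvi_curve <- function(t, a, b = NULL, c = NULL, d = NULL, k = NULL) {
  if (is.data.frame(a)) {
    p <- a
    stopifnot(nrow(p) == 1L)
    a <- p$a; b <- p$b; c <- p$c; d <- p$d; k <- p$k
  }
  validate_curve_params(a, b, c, d, k)
  z <- (t + d * log(k) - c) / d
  m <- (k + 1) / k
  # log1p(exp(z)) without overflow on the right tail
  l1pe <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  a + (b / k) * (k + 1)^m * exp(z - m * l1pe)
}

#' Reconstruct daily NDVI from fitted curve parameters
#'
#' Evaluates the fitted curve at every integer DOY in `[start, end]`,
#' the step that turns sparse, irregular acquisitions into the daily
#' series the predictor layouts are built from.
#'
#' @param params A one-row data frame with columns `a, b, c, d, k`
#'   ([curve_params()] or one row of [fit_curves()] output).
#' @param start,end Integer DOY bounds, `start <= end`.
#' @return A tibble with columns `doy` and `ndvi`,
#'   `end - start + 1` rows.
#' @export
daily_ndvi <- function(params, start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L,
            start == round(start), end == round(end))
  if (start > end) stop("start must be <= end", call. = FALSE)
  doy <- seq(as.integer(start), as.integer(end))
  tibble::tibble(doy = doy, ndvi = ndvi_curve(doy, params))
}
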