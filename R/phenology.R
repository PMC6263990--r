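#' Extract phenological characteristics from a fitted NDVI curve
#'
#' Computes the three characteristic points of the seasonal curve and the
#' NDVI values there: the left inflection (time of maximum growth rate),
#' the right inflection (time of maximum withering rate) and the seasonal
#' maximum. In the curve's `n`-parameterisation the peak sits at
#' `n = k`, i.e. `t_max = c` with `ndvi_max = a + b`, and the second
#' derivative vanishes at the roots of
#' `n^2 - k (k + 3) n + k^2 = 0`, i.e.
#' `n = (k/2) [(k + 3) +/- sqrt((k + 3)^2 - 4)]`, mapped back to time by
#' `t = c - d ln k + d ln n`. Both roots are positive for every `k > 0`,
#' so the ordering `t_inf_1 < t_max < t_inf_2` always holds.
#'
#' @param params A data frame with columns `a, b, c, d, k`; one row per
#'   fitted pixel ([curve_params()] or [fit_curves()] output). Rows with
#'   `converged == FALSE` (if present) are dropped with a message.
#' @return A tibble with one row per input row: any identifier columns
#'   (`pixel_id`, `crop`) carried through, plus `t_inf_1`, `t_inf_2`,
#'   `t_max` (DOY) and `ndvi_inf_1`, `ndvi_inf_2`, `ndvi_max`.
#' @examples
#' extract_phenology(curve_params(0.12, 0.68, 220, 15, 1))
#' @export
extract_phenology <- function(params) {
  stopifnot(is.data.frame(params),
            all(c("a", "b", "c", "d", "k") %in% names(params)))
  p <- params
  if ("converged" %in% names(p) && any(!is.na(p$converged) & !p$converged)) {
    n_bad <- sum(!is.na(p$converged) & !p$converged)
    message("dropping ", n_bad, " unconverged fit(s)")
    p <- p[is.na(p$converged) | p$converged, , drop = FALSE]
  }
  validate_curve_params(p$a, p$b, p$c, p$d, p$k)
  k <- p$k
  disc <- sqrt((k + 3)^2 - 4)
  n1 <- (k / 2) * ((k + 3) - disc)
  n2 <- (k / 2) * ((k + 3) + disc)
  t1 <- p$c - p$d * log(k) + p$d * log(n1)
  t2 <- p$c - p$d * log(k) + p$d * log(n2)
  id_cols <- intersect(c("pixel_id", "crop"), names(p))
  out <- tibble::as_tibble(p[, id_cols, drop = FALSE])
  out$t_inf_1 <- t1
  out$t_inf_2 <- t2
  out$t_max <- p$c
  out$ndvi_inf_1 <- ndvi_curve_vec(t1, p)
  out$ndvi_inf_2 <- ndvi_curve_vec(t2, p)
  out$ndvi_max <- p$a + p$b
  out
}

# rowwise curve evaluation: t[i] under parameter row i
ndvi_curve_vec <- function(t, p) {
  z <- (t + p$d * log(p$k) - p$c) / p$d
  m <- (p$k + 1) / p$k
  l1pe <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  p$a + (p$b / p$k) * (p$k + 1)^m * exp(z - m * l1pe)
}
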