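#' Plot a scene's crop mask
#'
#' @param object A [simulate_scene()] bundle.
#' @param ... Unused.
#' @return A ggplot: crop mask tiles with county boundaries implied by
#'   the county facet label.
#' @method autoplot scene_bundle
#' @export
autoplot.scene_bundle <- function(object, ...) {
  ggplot2::ggplot(object$pixels,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$crop)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Synthetic crop mask", x = NULL, y = NULL,
                  fill = "crop") +
    ggplot2::theme_minimal()
}

#' Plot one pixel's NDVI observations and fitted curve
#'
#' @param observations Long observation table (`pixel_id, doy, ndvi`).
#' @param params Fitted parameter table ([fit_curves()] output).
#' @param pixel_id Pixel to plot.
#' @return A ggplot of observed points with the fitted daily curve and
#'   the three phenological characteristic points.
#' @export
plot_curve_fit <- function(observations, params, pixel_id) {
  obs <- observations[observations$pixel_id == pixel_id, , drop = FALSE]
  par <- params[params$pixel_id == pixel_id, , drop = FALSE]
  stopifnot(nrow(obs) > 0L, nrow(par) == 1L, isTRUE(par$converged))
  grid <- daily_ndvi(par, floor(min(obs$doy)), ceiling(max(obs$doy)))
  ph <- extract_phenology(par)
  pts <- tibble::tibble(
    doy = c(ph$t_inf_1, ph$t_max, ph$t_inf_2),
    ndvi = c(ph$ndvi_inf_1, ph$ndvi_max, ph$ndvi_inf_2),
    what = c("left inflection", "peak", "right inflection"))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$doy, y = .data$ndvi)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "forestgreen") +
    ggplot2::geom_point(data = pts, ggplot2::aes(colour = .data$what),
                        size = 3) +
    ggplot2::labs(x = "day of year", y = "NDVI", colour = NULL,
                  title = sprintf("Pixel %s: asymmetric logistic fit",
                                  format(pixel_id))) +
    ggplot2::theme_minimal()
}

#' Plot a predicted yield map
#'
#' @param yield_map Output of [predict_yield_map()] (needs `row`, `col`,
#'   `yield`).
#' @return A ggplot raster of yields; no-data pixels are blank.
#' @export
plot_yield_map <- function(yield_map) {
  stopifnot(all(c("row", "col", "yield") %in% names(yield_map)))
  ggplot2::ggplot(yield_map[!is.na(yield_map$yield), ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$yield)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "yield (t/ha)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Estimated pixel yields") +
    ggplot2::theme_minimal()
}

#' Plot per-predictor importance of a yield model
#'
#' @param object A [fit_yield_rf()] model.
#' @param ... Unused.
#' @return A ggplot bar chart of permutation importance (%IncMSE).
#' @method autoplot yield_model
#' @export
autoplot.yield_model <- function(object, ...) {
  imp <- tidy(object)
  imp$term <- stats::reorder(imp$term, imp$pct_inc_mse)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$pct_inc_mse,
                                    y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "% increase in MSE when permuted", y = NULL,
      title = sprintf("%s, model %d: predictor importance",
                      object$spec$crop, object$spec$model_id)) +
    ggplot2::theme_minimal()
}
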