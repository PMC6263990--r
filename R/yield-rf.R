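#' Random-forest configuration
#'
#' The three forest parameters that matter for regression, at their
#' conventional defaults: `ntree = 500` trees, `mtry` equal to one third
#' of the predictor count (at least 1), and terminal `nodesize = 1`.
#'
#' @param ntree Number of trees (>= 1).
#' @param mtry Predictors tried per split; `NULL` means `max(1, floor(p/3))`
#'   resolved at fit time.
#' @param nodesize Minimum terminal node size (>= 1).
#' @param seed Integer RNG seed for tree growing.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(ntree = 500L, mtry = NULL, nodesize = 1L, seed = 1L) {
  stopifnot(ntree >= 1, nodesize >= 1, is.null(mtry) || mtry >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "rf_config")
}

#' Calibrate a per-crop random-forest yield model
#'
#' Trains a mean-of-trees regression forest mapping one predictor layout
#' to measured pixel yields (t/ha). Pixel-scale calibration -- attaching
#' measured yields to individual pixels rather than administrative
#' averages -- is what lets the model be applied back at pixel resolution.
#'
#' @param data A data frame holding one row per calibration pixel: the
#'   predictor columns named by `spec` plus the response column.
#' @param spec A [model_spec()] naming the predictor columns.
#' @param yield_col Name of the response column (default `"yield"`).
#' @param config An [rf_config()].
#' @return An object of class `yield_model` wrapping the fitted forest and
#'   training metadata. Supports [predict()], [tidy()] (per-predictor
#'   importance) and [glance()] (training-fit summary).
#' @export
fit_yield_rf <- function(data, spec, yield_col = "yield",
                         config = rf_config()) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"),
            inherits(config, "rf_config"))
  missing_cols <- setdiff(c(spec$predictors, yield_col), names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.data.frame(data[, spec$predictors, drop = FALSE])
  y <- data[[yield_col]]
  if (anyNA(X) || anyNA(y)) stop("missing values in training data",
                                 call. = FALSE)
  if (nrow(X) < 50L) {
    stop("at least 50 calibration pixels are required", call. = FALSE)
  }
  p <- length(spec$predictors)
  mtry <- if (is.null(config$mtry)) max(1L, p %/% 3L) else min(config$mtry, p)
  forest <- withr::with_seed(config$seed,
    randomForest::randomForest(
      x = X, y = y, ntree = config$ntree, mtry = mtry,
      nodesize = config$nodesize, importance = TRUE))
  fitted_train <- stats::predict(forest, X)
  structure(
    list(forest = forest, spec = spec, config = config,
         n_train = nrow(X), mtry = mtry,
         y_range = range(y),
         train_r2 = if (stats::sd(y) == 0 || stats::sd(fitted_train) == 0)
           NA_real_ else metrics(y, fitted_train, p = p)$r2),
    class = "yield_model"
  )
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf(
    "<yield_model> %s, model %d (%d predictors), %d pixels, %d trees\n",
    x$spec$crop, x$spec$model_id, length(x$spec$predictors),
    x$n_train, x$config$ntree))
  cat(sprintf("  training R^2 = %.3f\n", x$train_r2))
  invisible(x)
}

#' Predict pixel yields from a calibrated model
#'
#' Columns are matched to the model's predictors by name, never by
#' position, so column order in `newdata` is irrelevant.
#'
#' @param object A [fit_yield_rf()] model.
#' @param newdata Data frame containing all predictor columns.
#' @param ... Unused.
#' @return Numeric vector of yields (t/ha), one per row of `newdata`.
#' @export
predict.yield_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$spec$predictors, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks predictors: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(newdata[, object$spec$predictors, drop = FALSE])
  unname(stats::predict(object$forest, X))
}

#' Map predicted yields over a crop mask
#'
#' Joins predictions onto the scene's pixel table: pixels of the model's
#' crop that have a predictor row get a yield; all other pixels get `NA`
#' (no-data).
#'
#' @param model A [fit_yield_rf()] model.
#' @param predictors Predictor table with `pixel_id` column
#'   (from [build_predictors()]).
#' @param pixels Pixel table with `pixel_id, row, col, crop` columns
#'   (e.g. `scene$pixels`).
#' @return A tibble `pixel_id, row, col, crop, yield` covering every
#'   pixel of `pixels`; `yield` is `NA` off the model's crop.
#' @export
predict_yield_map <- function(model, predictors, pixels) {
  stopifnot(inherits(model, "yield_model"),
            "pixel_id" %in% names(predictors),
            all(c("pixel_id", "row", "col", "crop") %in% names(pixels)))
  crop_px <- pixels$pixel_id[pixels$crop == model$spec$crop]
  pred <- predictors[predictors$pixel_id %in% crop_px, , drop = FALSE]
  out <- tibble::as_tibble(pixels[, c("pixel_id", "row", "col", "crop")])
  out$yield <- NA_real_
  if (nrow(pred) > 0L) {
    yhat <- predict(model, pred)
    out$yield[match(pred$pixel_id, out$pixel_id)] <- yhat
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-predictor importance of a yield model
#'
#' @param x A [fit_yield_rf()] model.
#' @param ... Unused.
#' @return A tibble `term, pct_inc_mse, inc_node_purity`, one row per
#'   predictor, ordered as in the model spec.
#' @method tidy yield_model
#' @export
tidy.yield_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(term = rownames(imp),
                 pct_inc_mse = imp[, "%IncMSE"],
                 inc_node_purity = imp[, "IncNodePurity"])
}

#' One-row summary of a yield model fit
#'
#' @param x A [fit_yield_rf()] model.
#' @param ... Unused.
#' @return A one-row tibble: crop, model id, predictor count, training
#'   size, forest settings, training and out-of-bag R-squared.
#' @method glance yield_model
#' @export
glance.yield_model <- function(x, ...) {
  oob <- x$forest$rsq[length(x$forest$rsq)]
  tibble::tibble(crop = x$spec$crop, model_id = x$spec$model_id,
                 p = length(x$spec$predictors), n_train = x$n_train,
                 ntree = x$config$ntree, mtry = x$mtry,
                 train_r2 = x$train_r2, oob_r2 = oob)
}
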