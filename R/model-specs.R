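#' Predictor layout for one of the eight yield models
#'
#' Returns the ordered predictor names for the requested model and crop.
#' The eight layouts combine daily-reconstructed NDVI samples (`N_<doy>`)
#' with phenological characteristics and curve-shape parameters:
#'
#' * model 1: NDVI every 5 days across the crop's growth period;
#' * model 2: NDVI every 10 days;
#' * model 3: model 2 plus `t_inf_1`, `t_inf_2`, `t_max`;
#' * model 4: model 3 plus curve parameters `d` and `k`;
#' * model 5: NDVI every 10 days up to DOY 210 only (about 50 days
#'   before harvest, for pre-harvest forecasting);
#' * model 6: model 5 plus `t_inf_1`;
#' * model 7: the six phenological indexes
#'   `N_inf_1, N_inf_2, N_max, t_inf_1, t_inf_2, t_max`;
#' * model 8: model 7 plus `d` and `k`.
#'
#' The NDVI grid covers the crop's growth period: DOY 120-260 for maize,
#' and 160-260 for sunflower (models 1-6 for sunflower start at `N_160`;
#' models 7-8 contain no NDVI grid and are identical across crops).
#'
#' @param model_id Integer 1-8.
#' @param crop `"maize"` or `"sunflower"`.
#' @return An object of class `model_spec`: a list with `model_id`,
#'   `crop` and `predictors` (ordered character vector).
#' @examples
#' model_spec(5, "maize")
#' @export
model_spec <- function(model_id, crop = c("maize", "sunflower")) {
  crop <- match.arg(crop)
  if (length(model_id) != 1L || !model_id %in% 1:8) {
    stop("model_id must be a single integer in 1..8", call. = FALSE)
  }
  model_id <- as.integer(model_id)
  start <- if (crop == "maize") 120L else 160L
  grid5 <- paste0("N_", seq(start, 260L, by = 5L))
  grid10 <- paste0("N_", seq(start, 260L, by = 10L))
  grid10_early <- paste0("N_", seq(start, 210L, by = 10L))
  pheno_t <- c("t_inf_1", "t_inf_2", "t_max")
  pheno6 <- c("N_inf_1", "N_inf_2", "N_max", pheno_t)
  predictors <- switch(model_id,
    grid5,                               # 1
    grid10,                              # 2
    c(grid10, pheno_t),                  # 3
    c(grid10, pheno_t, "d", "k"),        # 4
    grid10_early,                        # 5
    c(grid10_early, "t_inf_1"),          # 6
    pheno6,                              # 7
    c(pheno6, "d", "k")                  # 8
  )
  structure(
    list(model_id = model_id, crop = crop, predictors = predictors),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> model %d, %s: %d predictors\n",
              x$model_id, x$crop, length(x$predictors)))
  cat(" ", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a predictor table for a model layout
#'
#' Builds the wide per-pixel predictor table for one [model_spec()] from
#' fitted curve parameters and extracted phenology. `N_<doy>` entries are
#' taken from the fitted curve's daily reconstruction (raw acquisitions do
#' not align to the layout's DOY grid); phenology entries come from
#' [extract_phenology()]; `d` and `k` are copied from the fit.
#' Unconverged pixels are excluded with a message.
#'
#' @param params Output of [fit_curves()] (columns `pixel_id`,
#'   `a, b, c, d, k`, optionally `converged`).
#' @param spec A [model_spec()].
#' @param phenology Optional pre-computed [extract_phenology()] output;
#'   computed from `params` when omitted.
#' @return A tibble: `pixel_id` plus one column per predictor, in spec
#'   order; all values finite.
#' @export
build_predictors <- function(params, spec, phenology = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(params),
            "pixel_id" %in% names(params))
  p <- params
  if ("converged" %in% names(p)) {
    bad <- !is.na(p$converged) & !p$converged | is.na(p$a)
    if (any(bad)) {
      message("excluding ", sum(bad), " pixel(s) without a converged fit")
      p <- p[!bad, , drop = FALSE]
    }
  }
  if (is.null(phenology)) phenology <- extract_phenology(p)
  stopifnot(identical(phenology$pixel_id, p$pixel_id))

  out <- tibble::tibble(pixel_id = p$pixel_id)
  for (name in spec$predictors) {
    out[[name]] <- if (grepl("^N_[0-9]+$", name)) {
      ndvi_curve_vec(as.numeric(sub("^N_", "", name)), p)
    } else {
      switch(name,
        N_inf_1 = phenology$ndvi_inf_1,
        N_inf_2 = phenology$ndvi_inf_2,
        N_max   = phenology$ndvi_max,
        t_inf_1 = phenology$t_inf_1,
        t_inf_2 = phenology$t_inf_2,
        t_max   = phenology$t_max,
        d = p$d,
        k = p$k,
        stop("unknown predictor name: ", name, call. = FALSE)
      )
    }
  }
  stopifnot(all(is.finite(as.matrix(out[spec$predictors]))))
  out
}
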