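#' Run the full simulate-fit-predict-evaluate pipeline
#'
#' Orchestrates one reproducible end-to-end run: simulate a scene, fit
#' the seasonal curve for every crop pixel and season, build the
#' requested predictor layouts, calibrate one forest per (crop, model),
#' map yields, aggregate to county production, score against the scene's
#' county truth and rank the models per crop. All artifacts are written
#' under `out_dir` and listed, with MD5 checksums, in `manifest.json`,
#' so identical configuration and seeds reproduce identical checksums.
#'
#' @param out_dir Output directory.
#' @param config A [scene_config()] (its `seed` drives the scene).
#' @param priors List of [crop_priors()].
#' @param crops Crops to model.
#' @param model_ids Predictor layouts to run (subset of 1-8).
#' @param rf An [rf_config()] (its `seed` drives forest training).
#' @param points Named sampling-point counts per crop for calibration.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list. Key artifacts per crop x model:
#'   `params_<crop>.csv`, `predictors_<crop>_m<id>.csv`,
#'   `yield_map_<crop>_m<id>.csv`, `county_production_<crop>_m<id>.csv`,
#'   plus `county_metrics.csv` and `model_ranking.csv`.
#' @export
run_pipeline <- function(out_dir, config = scene_config(),
                         priors = list(crop_priors("maize"),
                                       crop_priors("sunflower")),
                         crops = c("maize", "sunflower"),
                         model_ids = c(2L, 5L, 7L, 8L),
                         rf = rf_config(),
                         points = c(maize = 34L, sunflower = 54L),
                         quiet = FALSE) {
  if (length(model_ids) == 0L) {
    stop("model_ids must name at least one model", call. = FALSE)
  }
  stopifnot(all(model_ids %in% 1:8), all(crops %in% names(points)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[phenoyield] ", sprintf(...))
  t0 <- Sys.time()

  say("simulate: %dx%d grid, seed %d", config$grid_height,
      config$grid_width, config$seed)
  scene <- simulate_scene(config, priors)
  files <- write_scene(scene, out_dir)

  calib <- calibration_set(scene, points = points[crops])
  county_metrics <- list(); rankings <- list()

  for (cr in crops) {
    say("fit: %s curves", cr)
    obs <- dplyr::filter(scene$observations, .data$crop == cr)
    params_years <- obs |>
      dplyr::group_by(year = .data$year) |>
      dplyr::group_modify(~ fit_curves(.x)) |>
      dplyr::ungroup()
    n_drop <- sum(!params_years$converged)
    say("fit: %s done, %d pixel-season fits, %d dropped",
        cr, nrow(params_years), n_drop)
    pfile <- file.path(out_dir, paste0("params_", cr, ".csv"))
    utils::write.csv(params_years, pfile, row.names = FALSE)
    files[paste0("params_", cr)] <- pfile

    calib_cr <- dplyr::filter(calib, .data$crop == cr)
    for (mid in model_ids) {
      spec <- model_spec(mid, cr)
      per_year <- lapply(sort(unique(params_years$year)), function(yr) {
        par_y <- dplyr::filter(params_years, .data$year == yr,
                               .data$converged)
        X <- build_predictors(par_y, spec)
        train <- dplyr::inner_join(X, calib_cr[, c("pixel_id", "yield")],
                                   by = "pixel_id")
        model <- fit_yield_rf(train, spec, config = rf)
        ymap <- predict_yield_map(model, X, scene$pixels)
        est <- aggregate_production(ymap, scene$pixels,
                                    config$pixel_area_ha)
        est$year <- yr
        list(map = dplyr::mutate(ymap, year = yr), est = est)
      })
      ymap <- dplyr::bind_rows(lapply(per_year, `[[`, "map"))
      est <- dplyr::bind_rows(lapply(per_year, `[[`, "est"))
      tag <- paste0(cr, "_m", mid)
      mfile <- file.path(out_dir, paste0("yield_map_", tag, ".csv"))
      utils::write.csv(ymap[!is.na(ymap$yield), ], mfile, row.names = FALSE)
      files[paste0("yield_map_", tag)] <- mfile
      cfile <- file.path(out_dir, paste0("county_production_", tag, ".csv"))
      utils::write.csv(est, cfile, row.names = FALSE)
      files[paste0("county_production_", tag)] <- cfile

      # county validation: estimated vs true production, p = 1
      joined <- dplyr::inner_join(
        est, scene$counties,
        by = c("year", "county", "crop"), suffix = c("_est", "_true"))
      m <- metrics(joined$production_true, joined$production_est, p = 1)
      m_yield <- metrics(joined$mean_yield_true, joined$mean_yield_est,
                         p = 1)
      county_metrics[[tag]] <- tibble::tibble(
        crop = cr, model_id = mid, year = NA_integer_, level = "production",
        rmse = m$rmse, re = m$re, r2 = m$r2, adj_r2 = m$adj_r2)
      county_metrics[[paste0(tag, "_yield")]] <- tibble::tibble(
        crop = cr, model_id = mid, year = NA_integer_, level = "mean_yield",
        rmse = m_yield$rmse, re = m_yield$re, r2 = m_yield$r2,
        adj_r2 = m_yield$adj_r2)
      # per-year county mean-yield metrics feed the ranking
      per_year_m <- joined |>
        dplyr::group_by(year = .data$year) |>
        dplyr::group_modify(~ metrics(.x$mean_yield_true,
                                      .x$mean_yield_est, p = 1)) |>
        dplyr::ungroup() |>
        dplyr::mutate(crop = cr, model_id = mid)
      rankings[[tag]] <- per_year_m
      say("model %d (%s): county production RE %.1f%%", mid, cr, m$re)
    }
  }

  cm <- dplyr::bind_rows(county_metrics)
  cmfile <- file.path(out_dir, "county_metrics.csv")
  utils::write.csv(cm, cmfile, row.names = FALSE)
  files["county_metrics"] <- cmfile

  ranking <- dplyr::bind_rows(rankings) |>
    dplyr::group_by(crop = .data$crop) |>
    dplyr::group_modify(~ rank_models(.x)) |>
    dplyr::ungroup()
  rfile <- file.path(out_dir, "model_ranking.csv")
  utils::write.csv(ranking, rfile, row.names = FALSE)
  files["model_ranking"] <- rfile

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    scene_seed = config$seed, rf_seed = rf$seed,
    crops = crops, model_ids = as.integer(model_ids),
    config_hash = digest_obj(list(unclass(config),
                                  lapply(priors, unclass))),
    files = lapply(stats::setNames(as.character(files), names(files)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done in %.1f s", manifest$elapsed_s)
  invisible(manifest)
}

# content hash of an R object via its serialized MD5
digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
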