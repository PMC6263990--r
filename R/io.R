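#' Export a scene bundle to plain-text artifacts
#'
#' Writes the scene to `dir`: `pixels.csv` (mask + county partition),
#' `observations.csv` (long format: year, pixel_id, crop, doy, ndvi),
#' `truth.csv` (per-pixel true curve parameters and yields) and
#' `county_truth.csv`. If the \pkg{tiff} package is available, the crop
#' mask, county map and year-1 true-yield map are also written as
#' single-band float TIFF rasters with a `geotransform.txt` sidecar
#' holding the synthetic affine transform (origin 0,0; 30 m pixels).
#'
#' @param scene A [simulate_scene()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    pixels = file.path(dir, "pixels.csv"),
    observations = file.path(dir, "observations.csv"),
    truth = file.path(dir, "truth.csv"),
    county_truth = file.path(dir, "county_truth.csv")
  )
  utils::write.csv(scene$pixels, files["pixels"], row.names = FALSE)
  utils::write.csv(scene$observations, files["observations"],
                   row.names = FALSE)
  utils::write.csv(scene$truth, files["truth"], row.names = FALSE)
  utils::write.csv(scene$counties, files["county_truth"], row.names = FALSE)

  if (requireNamespace("tiff", quietly = TRUE)) {
    h <- scene$config$grid_height; w <- scene$config$grid_width
    as_grid <- function(v) matrix(v, nrow = h, ncol = w, byrow = TRUE)
    crop_code <- match(scene$pixels$crop,
                       c("none", "maize", "sunflower", "other")) - 1L
    y1 <- scene$truth[scene$truth$year == 1L, ]
    ymap <- rep(NA_real_, h * w)
    ymap[y1$pixel_id] <- y1$yield
    rasters <- list(
      "crop_mask.tif" = as_grid(crop_code / 255),
      "county_map.tif" = as_grid(scene$pixels$county / 255),
      "true_yield.tif" = as_grid(ifelse(is.na(ymap), 0, ymap / 1e4 + 0.5))
    )
    for (nm in names(rasters)) {
      path <- file.path(dir, nm)
      tiff::writeTIFF(rasters[[nm]], path, bits.per.sample = 32L)
      files[nm] <- path
    }
    gt <- file.path(dir, "geotransform.txt")
    writeLines(c("# synthetic affine transform: x0 y0 dx dy rot1 rot2",
                 "0 0 30 -30 0 0",
                 "# crop_mask codes: 0 none, 1 maize, 2 sunflower, 3 other",
                 "# crop_mask/county stored as code/255;",
                 "# true_yield stored as (t/ha)/1e4 + 0.5, no-data 0"),
               gt)
    files["geotransform"] <- gt
  }
  invisible(files)
}

#' Read a long-format observation table
#'
#' @param path CSV with columns `pixel_id, doy, ndvi` (and optionally
#'   `year`, `crop`).
#' @return A tibble.
#' @export
read_observations <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write or read a pipeline configuration
#'
#' Round-trips a [scene_config()] plus per-crop [crop_priors()] through a
#' structured YAML file, the on-disk configuration format of the
#' command-line pipeline.
#'
#' @param config A [scene_config()].
#' @param priors List of [crop_priors()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns `list(config =, priors =)`.
#' @export
write_run_config <- function(config, priors, path) {
  stopifnot(inherits(config, "scene_config"))
  obj <- list(
    scene = unclass(config),
    priors = lapply(priors, function(p) {
      p <- unclass(p)
      p$yield_link <- as.list(p$yield_link)
      p
    })
  )
  obj$scene$crop_fractions <- as.list(config$crop_fractions)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sc <- obj$scene
  config <- scene_config(
    grid_height = sc$grid_height, grid_width = sc$grid_width,
    pixel_area_ha = sc$pixel_area_ha, n_counties = sc$n_counties,
    crop_fractions = unlist(sc$crop_fractions), n_years = sc$n_years,
    seed = sc$seed, revisit_days = sc$revisit_days,
    window = unlist(sc$window), cloud_dropout = sc$cloud_dropout,
    noise_sd = sc$noise_sd, field_size = sc$field_size)
  priors <- lapply(obj$priors, function(p) {
    crop_priors(p$crop, a = unlist(p$a), b = unlist(p$b),
                c_mean = p$c_mean, c_spread = p$c_spread,
                d = unlist(p$d), k = unlist(p$k),
                growth_window = unlist(p$growth_window),
                yield_link = unlist(p$yield_link),
                yield_noise_sd = p$yield_noise_sd)
  })
  list(config = config, priors = priors)
}
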