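# Shared fixtures: everything is generated in code at test time.

# a small district that still contains all four counties and both crops
small_scene <- function(seed = 101, ...) {
  simulate_scene(scene_config(grid_height = 48, grid_width = 48,
                              seed = seed, ...))
}

# exact observations on a known curve, optionally noisy
series_on_curve <- function(a = 0.12, b = 0.68, c = 221, d = 16, k = 1.3,
                            doy = seq(90, 290, by = 2),
                            noise_sd = 0, seed = NULL) {
  clean <- ndvi_curve(doy, a, b, c, d, k)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    clean <- clean + stats::rnorm(length(doy), 0, noise_sd)
  }
  list(doy = doy, ndvi = clean,
       truth = c(a = a, b = b, c = c, d = d, k = k))
}

# independent numeric phenology oracle: symbolic differentiation of the
# curve expression (R's D(), applied twice) + uniroot/optimize; shares no
# algebra with the closed forms in extract_phenology().
curve_expr <- quote(
  a + (b / k) * (k + 1)^((k + 1) / k) *
    exp((t + d * log(k) - c) / d) *
    (1 + exp((t + d * log(k) - c) / d))^(-(k + 1) / k)
)
curve_d1 <- D(curve_expr, "t")
curve_d2 <- D(D(curve_expr, "t"), "t")

numeric_phenology <- function(a, b, c, d, k, tol = 1e-10) {
  env <- list(a = a, b = b, c = c, d = d, k = k)
  f2 <- function(t) eval(curve_d2, c(env, list(t = t)))
  f1 <- function(t) eval(curve_d1, c(env, list(t = t)))
  t_max <- stats::uniroot(f1, c(c - 12 * d, c + 12 * d), tol = tol)$root
  t1 <- stats::uniroot(f2, c(c - 12 * d, t_max), tol = tol)$root
  t2 <- stats::uniroot(f2, c(t_max, c + 12 * d), tol = tol)$root
  c(t_inf_1 = t1, t_max = t_max, t_inf_2 = t2)
}

# predictor-table fixture with model-7 column names and a smooth
# deterministic response
pheno_training_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  df <- tibble::tibble(
    N_inf_1 = runif(n, 0.40, 0.60), N_inf_2 = runif(n, 0.40, 0.60),
    N_max = runif(n, 0.60, 0.90),
    t_inf_1 = runif(n, 195, 210), t_inf_2 = runif(n, 230, 245),
    t_max = runif(n, 210, 230))
  df$yield <- 2 + 10 * df$N_max + 0.05 * (df$t_inf_2 - df$t_inf_1)
  df
}
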