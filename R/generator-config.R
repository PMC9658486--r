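#' Configuration of the synthetic-data generator
#'
#' Bundles every tunable of the synthetic destructive-harvest /
#' UAV-photogrammetry generator. Defaults reproduce the statistical structure
#' of the published campaigns: marginal ranges matching the summary envelopes
#' (see [reference_ranges()]), total mass scaling with plant volume to the
#' power 0.75, a foliage+branch mass fraction (FBMF) that declines with tree
#' size down to a plateau of 0.3, and a litter~SOM squared correlation near
#' 0.72.
#'
#' @param n_trees number of single trees to generate (default 37, the size of
#'   the single-tree campaign).
#' @param n_stands number of 25 m2 stand plots (default 11).
#' @param seed integer seed; together with the config it fully determines all
#'   outputs.
#' @param height_range_m `(min, max)` single-tree height range in metres.
#' @param scaling_exponent exponent `b` of the mass~volume power law
#'   `BM = k * V^b` (default 0.75, the metabolic-scaling value).
#' @param mass_coefficient multiplier `k` of the mass~volume power law
#'   (kg per m3^b; default 1.68, calibrated to the published mass and volume
#'   means).
#' @param fbmf_plateau FBMF plateau reached by large single trees (default 0.3).
#' @param fbmf_decline_exponent exponent of the gentle FBMF power decline
#'   with total dry mass (default 0.25, which makes the foliage+branch pool
#'   an exact `BM^0.75` power law at the default scaling exponent).
#' @param fbmf_knee_kg reference total dry mass at which the FBMF equals the
#'   plateau (default 11 kg, the median tree dry mass under defaults).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on masses (default 0.15). Noise draws have mean 1.
#' @param stems_range `(min, max)` stems per stand plot.
#' @param plot_side_m side of the square stand plot in metres (default 5).
#' @param grid_resolution_m canopy-height-grid cell size in metres (default
#'   0.02, i.e. a 2 cm/pixel terrain model).
#' @param sensor_noise_sd Gaussian sensor noise on grid heights, metres
#'   (default 0.05).
#' @param chemistry_means_ses per-tissue chemistry means/SEs; defaults to
#'   [reference_chemistry()].
#' @param litter_som_r2 target squared Pearson correlation between litter mass
#'   and soil organic matter across plots (default 0.72).
#' @return An object of class `"generator_config"` (a validated list).
#' @export
generator_config <- function(n_trees = 37,
                             n_stands = 11,
                             seed = 1L,
                             height_range_m = c(2.1, 10.6),
                             scaling_exponent = 0.75,
                             mass_coefficient = 1.68,
                             fbmf_plateau = 0.3,
                             fbmf_decline_exponent = 0.25,
                             fbmf_knee_kg = 11,
                             noise_cv = 0.15,
                             stems_range = c(3, 45),
                             plot_side_m = 5,
                             grid_resolution_m = 0.02,
                             sensor_noise_sd = 0.05,
                             chemistry_means_ses = reference_chemistry(),
                             litter_som_r2 = 0.72) {
  cfg <- list(
    n_trees = n_trees, n_stands = n_stands, seed = as.integer(seed),
    height_range_m = height_range_m,
    scaling_exponent = scaling_exponent,
    mass_coefficient = mass_coefficient,
    fbmf_plateau = fbmf_plateau,
    fbmf_decline_exponent = fbmf_decline_exponent,
    fbmf_knee_kg = fbmf_knee_kg,
    noise_cv = noise_cv,
    stems_range = stems_range,
    plot_side_m = plot_side_m,
    grid_resolution_m = grid_resolution_m,
    sensor_noise_sd = sensor_noise_sd,
    chemistry_means_ses = chemistry_means_ses,
    litter_som_r2 = litter_som_r2
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  chk_range <- function(r, nm) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("configuration error: '", nm, "' must be (min, max) with min < max",
           call. = FALSE)
  }
  chk_range(cfg$height_range_m, "height_range_m")
  chk_range(cfg$stems_range, "stems_range")
  if (any(cfg$height_range_m <= 0) || any(cfg$stems_range <= 0))
    stop("configuration error: non-positive range", call. = FALSE)
  if (cfg$n_trees < 0 || cfg$n_stands < 0)
    stop("configuration error: negative count", call. = FALSE)
  if (!(cfg$noise_cv >= 0))   # noise_cv = 0 allowed as the noiseless limit
    stop("configuration error: noise_cv must be >= 0", call. = FALSE)
  if (!(cfg$fbmf_plateau > 0 && cfg$fbmf_plateau < 1))
    stop("configuration error: fbmf_plateau must be in (0, 1)", call. = FALSE)
  if (cfg$plot_side_m < cfg$grid_resolution_m)
    stop("configuration error: plot smaller than one grid cell", call. = FALSE)
  if (cfg$scaling_exponent <= 0 || cfg$mass_coefficient <= 0)
    stop("configuration error: scaling law parameters must be positive",
         call. = FALSE)
  if (!(cfg$litter_som_r2 > 0 && cfg$litter_som_r2 < 1))
    stop("configuration error: litter_som_r2 must be in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-data generator configuration\n")
  cat(sprintf("  trees: %d   stands: %d   seed: %d\n",
              x$n_trees, x$n_stands, x$seed))
  cat(sprintf("  mass ~ %.3g * V^%.3g, noise CV %.3g\n",
              x$mass_coefficient, x$scaling_exponent, x$noise_cv))
  cat(sprintf("  FBMF curve: plateau %.2f, decline exponent %.3g, knee %.3g kg\n",
              x$fbmf_plateau, x$fbmf_decline_exponent, x$fbmf_knee_kg))
  cat(sprintf("  plots: %.3g m side, %.3g m cells, sensor sd %.3g m\n",
              x$plot_side_m, x$grid_resolution_m, x$sensor_noise_sd))
  invisible(x)
}

#' Read/write a generator configuration as JSON
#'
#' @param cfg a [generator_config()] object.
#' @param path file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns a `generator_config`.
#' @export
write_generator_config <- function(cfg, path) {
  validate_generator_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$chemistry_means_ses <- as.data.frame(raw$chemistry_means_ses,
                                           stringsAsFactors = FALSE)
  do.call(generator_config, raw)
}
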