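#' Generate synthetic stand plots with canopy height grids
#'
#' Emulates the clear-cut stand campaign: `n_stands` square plots of side
#' `plot_side_m`. Per plot, a stem count is drawn within `stems_range`, stems
#' are placed uniformly in the square and each carries a cone-shaped crown
#' (denser stands get shorter stems, reproducing the density-dependent
#' allocation of crowded shrubs). The canopy height grid is the per-cell
#' maximum crown height plus Gaussian sensor noise (`sensor_noise_sd`). Plot
#' geometry (`volume_m3`, `area_m2`, `H_mean`) is then measured from the grid
#' with the geometry module, exactly as a practitioner would from a terrain
#' model. Masses derive from summed per-stem cone volumes through the
#' configured power law, with the stand FBMF declining with stand mass and
#' density; `trunk_dry + fb_dry == total_dry` exactly. SOM and litter are
#' drawn from a bivariate Gaussian copula calibrated so that their squared
#' correlation targets `litter_som_r2`.
#'
#' @param config a [generator_config()].
#' @return list with elements
#'   \describe{
#'     \item{stands}{data.frame with columns `plot_id`, `area_m2`,
#'       `volume_m3`, `NrS`, `D_mean` (cm), `H_mean` (m), `trunk_dry`,
#'       `fb_dry`, `total_dry` (kg), `SOM_pct`, `litter_kg_m2`.}
#'     \item{grids}{named list of [height_grid()] objects (z0 = 0, the flat
#'       generated soil level).}
#'   }
#' @export
generate_stands <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_stands
  side <- config$plot_side_m
  cs <- config$grid_resolution_m
  ncell <- floor(side / cs)
  if (ncell < 1)
    stop("configuration error: plot smaller than one grid cell", call. = FALSE)
  if (n == 0) {
    empty <- data.frame(plot_id = character(0), area_m2 = numeric(0),
                        volume_m3 = numeric(0), NrS = integer(0),
                        D_mean = numeric(0), H_mean = numeric(0),
                        trunk_dry = numeric(0), fb_dry = numeric(0),
                        total_dry = numeric(0), SOM_pct = numeric(0),
                        litter_kg_m2 = numeric(0), stringsAsFactors = FALSE)
    return(list(stands = empty, grids = list()))
  }

  stands <- vector("list", n)
  grids <- vector("list", n)

  # plot-level latents: wide crown-volume spread (the harvested plots spanned
  # roughly 4-190 m3), stem count increasing with plot volume
  vp_all <- exp(log(50) + 0.75 * stats::qnorm(stats::runif(n, 0.05, 0.95)))
  vp_all <- pmin(pmax(vp_all, 12), 200)
  nrs <- round(9.5 * (vp_all / 50)^0.45 * exp(stats::rnorm(n, 0, 0.35)))
  nrs <- pmin(pmax(nrs, config$stems_range[1]), config$stems_range[2])
  s_fac <- exp(stats::rnorm(n, 0, 0.24))   # residual stature factor (D_mean)
  s_std <- if (n > 1 && stats::sd(log(s_fac)) > 0)
    (log(s_fac) - mean(log(s_fac))) / stats::sd(log(s_fac)) else rep(0, n)
  d_mean <- exp(log(17) + 0.25 * (0.5 * s_std + sqrt(0.75) * stats::rnorm(n)))
  d_mean <- pmin(pmax(d_mean, 7.5), 34)

  # SOM / litter joint draw (Gaussian copula, lognormal margins)
  rho <- sqrt(config$litter_som_r2) * 1.03   # offset the lognormal attenuation
  rho <- min(rho, 0.99)
  g1 <- stats::rnorm(n)
  g2 <- rho * g1 + sqrt(1 - rho^2) * stats::rnorm(n)
  som <- stats::qlnorm(stats::pnorm(g1), log(0.65), 0.32)
  som <- pmin(pmax(som, 0.3), 1.4)
  litter <- stats::qlnorm(stats::pnorm(g2), log(0.5), 0.55)
  litter <- pmin(pmax(litter, 0.02), 1.9)

  for (i in seq_len(n)) {
    k <- nrs[i]
    vp <- vp_all[i]   # total crown volume target (m3); stems scaled to it
    h_raw <- exp(stats::rnorm(k, log(3), 0.2))
    # narrow conic crowns: sparse canopy overlap, so the grid surface volume
    # tracks the summed stem volumes as it does over harvested quadrats
    r_raw <- 0.22 * h_raw * exp(stats::rnorm(k, 0, 0.10))
    v_raw <- pi * r_raw^2 * h_raw / 3
    sc <- (vp / sum(v_raw))^(1 / 3)
    h <- pmin(pmax(h_raw * sc, 0.5), 7.5)
    r <- pmin(pmax(r_raw * sc, 0.2), 2.8)
    margin <- min(0.6, side / 4)
    px <- stats::runif(k, margin, side - margin)
    py <- stats::runif(k, margin, side - margin)

    z <- .render_cones(px, py, h, r, side, cs)
    if (config$sensor_noise_sd > 0)
      z <- z + stats::rnorm(length(z), 0, config$sensor_noise_sd)
    g <- height_grid(matrix(z, ncell, ncell), cs,
                     plot_id = sprintf("S%02d", i), z0 = 0)

    v_stem <- pi * r^2 * h / 3
    # per-stem power law with density-dependent competition ((9.5/k)^0.25:
    # stems in denser stands carry less mass for the same crown volume) and a
    # crown-interpenetration discount (overlapping crown volume is shared
    # between neighbouring stems rather than filled by each)
    bm <- 0.70 * sum(config$mass_coefficient * v_stem^config$scaling_exponent) *
      (9.5 / k)^0.25 * .lognoise(1, config$noise_cv)
    bm <- min(max(bm, 13), 170)
    fbmf <- 0.52 - 1.5e-3 * bm - 1.5e-3 * k + stats::rnorm(1, 0, 0.025)
    fbmf <- min(max(fbmf, 0.24), 0.55)
    fb <- fbmf * bm
    trunk <- bm - fb

    stands[[i]] <- data.frame(
      plot_id = sprintf("S%02d", i),
      area_m2 = cover_area(g),
      volume_m3 = surface_volume(g),
      NrS = as.integer(k),
      D_mean = d_mean[i],
      H_mean = mean_height(g),
      trunk_dry = trunk, fb_dry = fb, total_dry = trunk + fb,
      SOM_pct = som[i], litter_kg_m2 = litter[i],
      stringsAsFactors = FALSE
    )
    grids[[i]] <- g
  }
  stands <- do.call(rbind, stands)
  names(grids) <- stands$plot_id
  list(stands = stands, grids = grids)
}

# Per-cell maximum height over a set of cone crowns, computed per stem over
# the bounding box of its base circle. Returns an ncell x ncell matrix as a
# vector (column-major, row 1 = north edge, matching height_grid()).
.render_cones <- function(px, py, h, r, side, cs) {
  ncell <- floor(side / cs)
  z <- matrix(0, ncell, ncell)
  xs <- (seq_len(ncell) - 0.5) * cs        # column centres (x)
  ys <- (ncell - seq_len(ncell) + 0.5) * cs  # row centres (y), row 1 = top
  for (j in seq_along(px)) {
    ci <- which(abs(xs - px[j]) <= r[j])
    ri <- which(abs(ys - py[j]) <= r[j])
    if (!length(ci) || !length(ri)) next
    d <- sqrt(outer((ys[ri] - py[j])^2, (xs[ci] - px[j])^2, "+"))
    zj <- h[j] * pmax(1 - d / r[j], 0)
    z[ri, ci] <- pmax(z[ri, ci], zj)
  }
  z
}
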