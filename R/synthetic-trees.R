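# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic FBMF curve: a gentle power decline through the plateau value
# at the knee mass, so the foliage+branch pool is an exact power law of total
# mass (FB = plateau * knee^eps * BM^(1-eps)) while the mass fraction itself
# levels off near the plateau for large trees.
.fbmf_curve <- function(bm, cfg) {
  f <- cfg$fbmf_plateau * (bm / cfg$fbmf_knee_kg)^(-cfg$fbmf_decline_exponent)
  pmin(pmax(f, 0.05), 0.85)
}

#' Generate a synthetic single-tree harvest table
#'
#' Draws `n_trees` destructively harvested trees whose joint structure mirrors
#' the field campaign: height `H`, basal diameter `D` and the two canopy
#' diameters `C1 >= C2` come from correlated lognormals calibrated to the
#' published envelopes; canopy area `A` and conic volume `V` follow from the
#' geometry module; total dry mass obeys the power law
#' `BM = k * V^b * eps` with multiplicative lognormal noise `eps` (mean 1, CV
#' `noise_cv`); the foliage+branch pool is `FBMF(BM) * BM` where the FBMF
#' declines with tree size down to the configured plateau; the trunk is the
#' remainder, and the foliage:branch split jitters around the 4.1:3.3 ratio
#' of the published compartment means.
#'
#' Per tree, `trunk_dry + fb_dry == total_dry` and
#' `foliage_dry + branch_dry == fb_dry` hold exactly.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `tree_id`, `H` (m), `D` (cm), `C1`, `C2`
#'   (m), `A` (m2), `V` (m3), `trunk_dry`, `branch_dry`, `foliage_dry`,
#'   `fb_dry`, `total_dry` (kg).
#' @export
#' @examples
#' trees <- generate_trees(generator_config(n_trees = 50, seed = 1))
#' head(trees)
generate_trees <- function(config) {
  validate_generator_config(config)
  n <- config$n_trees
  cols <- c("tree_id", "H", "D", "C1", "C2", "A", "V", "trunk_dry",
            "branch_dry", "foliage_dry", "fb_dry", "total_dry")
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$tree_id <- character(0)
    return(out)
  }
  set.seed(config$seed)

  # shared size factor induces the H-D-canopy correlation of real shrubs
  u  <- stats::rnorm(n)
  rho <- 0.85
  mix <- function(sd_ind) rho * u + sqrt(1 - rho^2) * stats::rnorm(n)

  hr <- config$height_range_m
  mu_H <- mean(log(hr)) + 0.05          # slight upward shift: sizes are skewed
  sd_H <- log(hr[2] / hr[1]) / 4 * 0.87
  H <- exp(mu_H + sd_H * mix())
  H <- pmin(pmax(H, hr[1] * 0.85), hr[2] * 1.02)

  D <- exp(log(8.0) + 0.52 * mix())      # basal diameter, cm
  r <- exp(log(1.45) + 0.26 * mix())     # mean canopy radius (C1+C2)/4, m
  asym <- abs(stats::rnorm(n, 0, 0.12))
  C1 <- 2 * r * (1 + asym)
  C2 <- 2 * r * (1 - asym)

  A <- canopy_area(C1, C2)
  V <- cone_volume(A, H)

  bm <- config$mass_coefficient * V^config$scaling_exponent *
    .lognoise(n, config$noise_cv)
  fbmf <- pmin(.fbmf_curve(bm, config) * .lognoise(n, config$noise_cv), 0.95)
  fb <- fbmf * bm
  trunk <- bm - fb

  # foliage:branch split around the published compartment means 4.1:3.3
  p_fol <- stats::rbeta(n, 4.1 * 12, 3.3 * 12)
  foliage <- p_fol * fb
  branch <- fb - foliage
  fb_sum <- foliage + branch
  total <- trunk + fb_sum

  data.frame(tree_id = sprintf("T%03d", seq_len(n)),
             H = H, D = D, C1 = C1, C2 = C2, A = A, V = V,
             trunk_dry = trunk, branch_dry = branch, foliage_dry = foliage,
             fb_dry = fb_sum, total_dry = total,
             stringsAsFactors = FALSE)
}
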