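#' Published summary envelopes for single trees and stands
#'
#' Min/max/mean envelopes of the allometric and biomass variables reported for
#' destructively harvested *Acacia longifolia*: 37 single trees and 11
#' clear-cut 25 m2 stand plots. These are the calibration targets of the
#' synthetic-data generator and the envelopes used by its validation checks.
#'
#' @param kind `"trees"` or `"stands"`.
#' @return A data.frame with columns `variable`, `min`, `max`, `mean` and
#'   `delta` (`max - min`). Units: volume m3, area m2, heights m, diameters
#'   cm, masses kg, SOM percent, litter kg/m2.
#' @export
#' @examples
#' reference_ranges("trees")
reference_ranges <- function(kind = c("trees", "stands")) {
  kind <- match.arg(kind)
  if (kind == "trees") {
    out <- data.frame(
      variable = c("V", "A", "H", "D", "trunk_dry", "branch_dry",
                   "foliage_dry", "fb_dry", "total_dry"),
      min  = c(2.4, 1.2, 2.1, 1.9, 0.3, 0.1, 0.2, 0.3, 0.7),
      max  = c(169.1, 24.6, 10.6, 25.5, 110.3, 11.2, 12, 23.2, 129.9),
      mean = c(26.9, 7.2, 4.9, 9.8, 12.5, 3.3, 4.1, 7.3, 19.8),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      variable = c("V", "A", "NrS", "D_mean", "H_mean", "trunk_dry",
                   "fb_dry", "total_dry", "SOM_pct", "litter_kg_m2"),
      min  = c(3.9, 1.2, 3, 7.2, 0.4, 4.3, 5.2, 9.5, 0.3, 0.01),
      max  = c(187.5, 29.2, 45, 34.1, 7, 133.6, 50.4, 184, 1.4, 1.9),
      mean = c(70.5, 15, 10.8, 19.9, 3, 50.2, 24.1, 74.4, 0.7, 0.7),
      stringsAsFactors = FALSE
    )
  }
  out$delta <- out$max - out$min
  out
}

#' Reference tissue chemistry table
#'
#' Mean (standard error) nutrient content and isotopic signatures of the
#' harvested tissues, as published for the destructive campaigns: per-tissue
#' carbon and nitrogen percent, phosphorus per-mil (trunk and foliage of
#' single trees only), and delta-13C / delta-15N. Used as the default
#' `chemistry_means_ses` of [generator_config()] and as the concentration
#' source for nutrient-pool extrapolation.
#'
#' @return data.frame with columns `unit` ("tree"/"stand"), `tissue`
#'   ("trunk", "branch", "foliage", "fb"), and `<analyte>_mean` /
#'   `<analyte>_se` for analytes `C_pct`, `N_pct`, `P_permil`, `d15N`, `d13C`.
#'   `NA` where the analyte was not measured for that tissue.
#' @export
reference_chemistry <- function() {
  data.frame(
    unit   = c("tree", "tree", "tree", "tree", "stand", "stand"),
    tissue = c("trunk", "branch", "foliage", "fb", "trunk", "fb"),
    C_pct_mean    = c(43.2, 45.1, 48.1, 47.7, 44.1, 47.2),
    C_pct_se      = c(0.1, 0.2, 0.2, 0.2, 0.7, 0.5),
    N_pct_mean    = c(0.6, 1.1, 2.3, 2.2, 0.6, 2.0),
    N_pct_se      = c(0.1, 0.1, 0.1, 0.1, 0.0, 0.1),
    P_permil_mean = c(0.8, NA, 2.4, NA, NA, NA),
    P_permil_se   = c(0.1, NA, 0.2, NA, NA, NA),
    d15N_mean     = c(-1.2, -1.7, -1.1, -1.2, -2.2, -2.1),
    d15N_se       = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.2),
    d13C_mean     = c(-27.5, -25.9, -28.4, -28.1, -27.5, -29.0),
    d13C_se       = c(0.2, 0.4, 0.2, 0.3, 0.2, 0.4),
    stringsAsFactors = FALSE
  )
}
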