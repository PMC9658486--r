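#' Elemental pool totals from compartment masses and tissue chemistry
#'
#' Extrapolates total carbon, nitrogen and phosphorus from per-compartment
#' dry masses and tissue concentrations: `E_tot = sum(mass * concentration)`
#' with percent concentrations divided by 100 and per-mil by 1000. Also
#' returns the total-biomass C/N ratio and the mass-fraction summary
#' (FBMF = fb / (fb + trunk), TMF = 1 - FBMF).
#'
#' Phosphorus is totalled only over compartments with a P value (published
#' chemistry reports P for trunk and foliage of single trees only); a
#' compartment with mass but entirely missing chemistry row raises an error
#' rather than silently contributing zero.
#'
#' @param masses named numeric vector of dry masses in kg; names from
#'   `trunk`, `branch`, `foliage`, `fb`. Use either `fb` or the
#'   `branch`/`foliage` pair, not both.
#' @param chem chemistry table with columns `tissue`, `C_pct`, `N_pct`,
#'   `P_permil` (rows as produced by [generate_chemistry()], possibly
#'   filtered to one sampling unit).
#' @return list of class `"pool_totals"`: `C_tot`, `N_tot`, `P_tot` (kg;
#'   `P_tot` is `NA` if no compartment has P), `CN_total`, `FBMF`, `TMF`.
#' @export
#' @examples
#' chem <- generate_chemistry(generator_config(seed = 1))
#' pool_totals(c(trunk = 100, fb = 30), chem[chem$unit == "stand", ])
pool_totals <- function(masses, chem) {
  if (is.null(names(masses)) || any(!nzchar(names(masses))))
    stop("masses must be a named vector", call. = FALSE)
  if (any(masses < 0)) stop("domain error: negative mass", call. = FALSE)
  if (all(c("fb", "branch") %in% names(masses)) ||
      all(c("fb", "foliage") %in% names(masses)))
    stop("provide either 'fb' or the branch/foliage pair, not both",
         call. = FALSE)

  fb_mass <- if ("fb" %in% names(masses)) masses[["fb"]] else
    sum(masses[names(masses) %in% c("branch", "foliage")])
  trunk_mass <- if ("trunk" %in% names(masses)) masses[["trunk"]] else 0
  if (fb_mass + trunk_mass <= 0)
    stop("domain error: total mass is zero, mass fractions undefined",
         call. = FALSE)

  conc <- function(tissue, col) {
    row <- chem[chem$tissue == tissue, , drop = FALSE]
    if (nrow(row) == 0)
      stop("missing chemistry for compartment '", tissue, "'", call. = FALSE)
    row[[col]][1]
  }
  tot <- function(col, scale) {
    vals <- vapply(names(masses), function(tis) conc(tis, col), numeric(1))
    if (all(is.na(vals))) return(NA_real_)
    contrib <- masses * vals / scale
    sum(contrib, na.rm = TRUE)
  }

  C_tot <- tot("C_pct", 100)
  N_tot <- tot("N_pct", 100)
  P_tot <- tot("P_permil", 1000)
  fbmf <- fb_mass / (fb_mass + trunk_mass)
  structure(list(C_tot = C_tot, N_tot = N_tot, P_tot = P_tot,
                 CN_total = C_tot / N_tot, FBMF = fbmf, TMF = 1 - fbmf),
            class = "pool_totals")
}

#' @export
print.pool_totals <- function(x, ...) {
  cat(sprintf("pool totals: C %.4g kg, N %.4g kg, P %s kg\n",
              x$C_tot, x$N_tot,
              ifelse(is.na(x$P_tot), "NA", format(signif(x$P_tot, 4)))))
  cat(sprintf("  C/N = %.4g, FBMF = %.3f, TMF = %.3f\n",
              x$CN_total, x$FBMF, x$TMF))
  invisible(x)
}

#' Append per-unit nutrient totals to a tree or stand table
#'
#' Computes `C_tot`, `N_tot` (and `P_tot` for trees) per row using group-mean
#' tissue chemistry, so nutrient responses can enter the model zoo.
#'
#' @param data tree table (columns `trunk_dry`, `branch_dry`, `foliage_dry`)
#'   or stand table (columns `trunk_dry`, `fb_dry`).
#' @param chem chemistry table ([generate_chemistry()] output) for the
#'   matching unit (`"tree"` or `"stand"`).
#' @param unit `"tree"` or `"stand"`.
#' @return `data` with `C_tot`, `N_tot` and (trees) `P_tot` columns added.
#' @export
add_nutrient_totals <- function(data, chem, unit = c("tree", "stand")) {
  unit <- match.arg(unit)
  chem <- chem[chem$unit == unit, , drop = FALSE]
  if (unit == "tree") {
    ms <- function(i) c(trunk = data$trunk_dry[i], branch = data$branch_dry[i],
                        foliage = data$foliage_dry[i])
  } else {
    ms <- function(i) c(trunk = data$trunk_dry[i], fb = data$fb_dry[i])
  }
  pools <- lapply(seq_len(nrow(data)), function(i) pool_totals(ms(i), chem))
  data$C_tot <- vapply(pools, `[[`, numeric(1), "C_tot")
  data$N_tot <- vapply(pools, `[[`, numeric(1), "N_tot")
  if (unit == "tree")
    data$P_tot <- vapply(pools, `[[`, numeric(1), "P_tot")
  data
}

#' Fit the biomass partitioning power law
#'
#' Shifted power fit `FB = a + b * BM^c` of the foliage+branch pool on total
#' dry biomass — the allometric partitioning relationship whose theoretical
#' exponent is 0.75. Delegates to the power machinery of the model zoo.
#'
#' @param BM numeric vector of total dry biomass (kg), positive, `n >= 4`.
#' @param FB numeric vector of foliage+branch dry mass (kg).
#' @return an `allom_fit` (family `power_sum`, single predictor); the
#'   exponent is `coefficients["c_V"]`.
#' @export
fit_partitioning <- function(BM, FB) {
  if (length(BM) < 4) stop("domain error: need n >= 4", call. = FALSE)
  if (any(BM <= 0)) stop("domain error: BM must be positive", call. = FALSE)
  df <- data.frame(V = BM, total_dry = FB)
  fit_model(model_spec("total", "V", "power_sum"), df)
}

#' Estimate the FBMF plateau of single trees
#'
#' Fits the segmented hinge regression of the foliage+branch mass fraction on
#' total dry biomass and returns the fitted FBMF at the breakpoint — the
#' plateau level reached by large trees when the right segment is flat.
#'
#' @param trees single-tree table with `fb_dry` and `total_dry`.
#' @return list with `plateau` (fitted FBMF at the breakpoint), `psi_kg`
#'   (breakpoint in kg of total biomass) and the underlying `segmented_fit`.
#' @export
estimate_fbmf_plateau <- function(trees) {
  fbmf <- trees$fb_dry / trees$total_dry
  fit <- fit_segmented(trees$total_dry, fbmf)
  list(plateau = fit$fitted_at_psi, psi_kg = fit$psi, fit = fit)
}

#' Dry mass from fresh mass
#'
#' @param fresh_kg fresh (wet) mass in kg.
#' @param dry_fraction dry-matter fraction in (0, 1): dry/fresh mass ratio
#'   determined from oven-dried subsamples.
#' @return dry mass in kg.
#' @export
#' @examples
#' dry_mass(100, 0.5)
dry_mass <- function(fresh_kg, dry_fraction) {
  if (any(!is.finite(dry_fraction)) || any(dry_fraction <= 0) ||
      any(dry_fraction >= 1))
    stop("domain error: dry_fraction must be in (0, 1)", call. = FALSE)
  if (any(fresh_kg < 0))
    stop("domain error: negative fresh mass", call. = FALSE)
  fresh_kg * dry_fraction
}
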