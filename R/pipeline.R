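#' Configuration for a full pipeline run
#'
#' Each dataset comes either from CSV paths or from the synthetic generator,
#' never both.
#'
#' @param generator a [generator_config()], or `NULL` when paths are given.
#' @param tree_csv,stand_csv,chemistry_csv input paths (used when
#'   `generator` is `NULL`).
#' @param out_dir output directory (created if missing).
#' @param delta_bic parsimony ladder width for [select_models()].
#' @param tree_responses,stand_responses responses for the selection tables.
#' @param subsampling list of settings for [r_curve()]: `n_max` or
#'   `n_values`, `reps`, `seed`.
#' @param cover_threshold_m vegetation cover threshold in metres.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(),
                       tree_csv = NULL, stand_csv = NULL,
                       chemistry_csv = NULL,
                       out_dir = tempfile("acaciabm_run_"),
                       delta_bic = 10,
                       tree_responses = c("total", "trunk", "foliage",
                                          "branches", "fb", "C_tot", "N_tot",
                                          "P_tot"),
                       stand_responses = c("total", "trunk", "fb", "litter",
                                           "SOM", "C_tot", "N_tot"),
                       subsampling = list(n_values = 1:30, reps = 500,
                                          seed = 1L),
                       cover_threshold_m = 0.30) {
  if (!is.null(generator) &&
      (!is.null(tree_csv) || !is.null(stand_csv)))
    stop("configuration error: give either a generator config or input ",
         "paths, not both", call. = FALSE)
  if (is.null(generator) && (is.null(tree_csv) || is.null(stand_csv)))
    stop("configuration error: without a generator, tree_csv and stand_csv ",
         "are required", call. = FALSE)
  structure(list(generator = generator, tree_csv = tree_csv,
                 stand_csv = stand_csv, chemistry_csv = chemistry_csv,
                 out_dir = out_dir, delta_bic = delta_bic,
                 tree_responses = tree_responses,
                 stand_responses = stand_responses,
                 subsampling = subsampling,
                 cover_threshold_m = cover_threshold_m),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full modelling pipeline
#'
#' Orchestrates generate (or load) -> geometry -> model zoo + selection ->
#' combined volumetric model -> FBMF segmented fit -> height-subsampling
#' curve -> nutrient pools, writing every result plus a reproducibility
#' manifest into `config$out_dir`. With a fixed generator seed the run is
#' bit-identical across repetitions.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results: `trees`, `stands`,
#'   `chemistry`, `tree_models`, `stand_models`, `combined`, `fbmf`,
#'   `curve`, `min_obs`, `out_dir`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$generator)) {
    trees <- .stage("generate", generate_trees(config$generator))
    st <- .stage("generate", generate_stands(config$generator))
    stands <- st$stands
    grids <- st$grids
    chem <- .stage("generate", generate_chemistry(config$generator))
  } else {
    trees <- .stage("load", read_table_csv(config$tree_csv))
    stands <- .stage("load", read_table_csv(config$stand_csv))
    grids <- NULL
    chem <- if (is.null(config$chemistry_csv)) NULL else
      .stage("load", read_table_csv(config$chemistry_csv))
  }

  needs_chem <- any(c("C_tot", "N_tot", "P_tot") %in%
                      c(config$tree_responses, config$stand_responses))
  if (needs_chem) {
    if (is.null(chem))
      stop("[stage nutrients] chemistry table required for nutrient ",
           "responses but none provided", call. = FALSE)
    trees <- .stage("nutrients", add_nutrient_totals(trees, chem, "tree"))
    stands <- .stage("nutrients", add_nutrient_totals(stands, chem, "stand"))
  }

  tree_tab <- .stage("select",
                     selection_table(trees, "trees", config$tree_responses,
                                     config$delta_bic))
  stand_tab <- .stage("select",
                      selection_table(stands, "stands",
                                      config$stand_responses,
                                      config$delta_bic))
  combined <- .stage("combined", fit_combined_volume_model(trees, stands))
  fbmf <- .stage("segment", estimate_fbmf_plateau(trees))

  curve <- min_obs <- NULL
  if (!is.null(grids)) {
    clouds <- lapply(grids, function(g) as.vector(g$z - g$z0))
    ss <- config$subsampling
    curve <- .stage("heightcurve",
                    r_curve(clouds, stands$total_dry,
                            n_values = if (!is.null(ss$n_values)) ss$n_values
                                       else seq_len(ss$n_max),
                            reps = ss$reps, seed = ss$seed,
                            plot_area_m2 = config$generator$plot_side_m^2))
    min_obs <- .stage("heightcurve", min_observations(curve))
  }

  write_table_csv(trees, od("trees.csv"))
  write_table_csv(stands, od("stands.csv"))
  if (!is.null(chem)) write_table_csv(chem, od("chemistry.csv"))
  write_table_csv(tree_tab, od("tree_models.csv"))
  write_table_csv(stand_tab, od("stand_models.csv"))
  write_fit_json(combined, od("combined_model.json"))
  jsonlite::write_json(list(plateau = fbmf$plateau, psi_kg = fbmf$psi_kg,
                            davies_p = fbmf$fit$davies_p,
                            degenerate = fbmf$fit$degenerate),
                       od("fbmf_segmented.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(curve)) {
    write_curve_csv(curve, od("height_curve.csv"))
    jsonlite::write_json(list(n_min = min_obs$n_min, psi = min_obs$psi,
                              flag = min_obs$flag,
                              reps = attr(curve, "reps"),
                              seed = attr(curve, "seed")),
                         od("min_observations.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("acaciabm")),
    generator_seed = if (!is.null(config$generator)) config$generator$seed,
    subsampling_seed = config$subsampling$seed,
    delta_bic = config$delta_bic,
    cover_threshold_m = config$cover_threshold_m,
    outputs = c("trees.csv", "stands.csv", "chemistry.csv",
                "tree_models.csv", "stand_models.csv", "combined_model.json",
                "fbmf_segmented.json", "height_curve.csv",
                "min_observations.json")
  )
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(trees = trees, stands = stands, chemistry = chem,
                 tree_models = tree_tab, stand_models = stand_tab,
                 combined = combined, fbmf = fbmf, curve = curve,
                 min_obs = min_obs, out_dir = config$out_dir))
}

#' Validate the combined volumetric model on the whole-plot harvest
#'
#' Applies a fitted (or published) combined model to the volume of a fully
#' harvested plot and compares the prediction with the harvest-measured dry
#' mass. All defaults are the published whole-plot figures: stand volume
#' 31,711 m3 from the terrain model, 52,847 kg of fresh biomass over the
#' weighbridge, dry-matter fraction 0.6031 from stand subsamples, and the
#' combined-model coefficients (6.297, 0.982).
#'
#' @param volume_m3 harvested plot volume (m3).
#' @param fresh_kg fresh harvested mass (kg).
#' @param dry_fraction dry-matter fraction in (0, 1).
#' @param coefficients `c(intercept, slope)` of the combined volumetric model.
#' @param measured_dry_kg optionally override the measured dry mass instead
#'   of computing `fresh_kg * dry_fraction`.
#' @return list: `predicted_kg`, `measured_kg`, `deviation_kg`,
#'   `deviation_pct` (100 x (measured - predicted) / measured).
#' @export
#' @examples
#' validate_worked_example()
validate_worked_example <- function(volume_m3 = 31711,
                                    fresh_kg = 52847,
                                    dry_fraction = 0.6031,
                                    coefficients = c(6.297, 0.982),
                                    measured_dry_kg = NULL) {
  predicted <- coefficients[1] + coefficients[2] * volume_m3
  measured <- if (is.null(measured_dry_kg)) dry_mass(fresh_kg, dry_fraction)
              else measured_dry_kg
  list(predicted_kg = predicted,
       measured_kg = measured,
       deviation_kg = measured - predicted,
       deviation_pct = 100 * (measured - predicted) / measured)
}
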