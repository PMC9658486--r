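#' Enumerate the candidate model zoo
#'
#' All non-empty predictor subsets (up to 3 predictors for single trees out
#' of V, A, H, D; up to 4 for stands out of V, A, H_mean, D_mean, NrS)
#' crossed with the three equation families: 42 specs per tree response, 90
#' per stand response.
#'
#' @param dataset_kind `"trees"` or `"stands"`.
#' @param response response name (see [model_spec()]).
#' @return list of [model_spec()] objects, deduplicated.
#' @export
enumerate_models <- function(dataset_kind = c("trees", "stands"), response) {
  dataset_kind <- match.arg(dataset_kind)
  preds <- if (dataset_kind == "trees") c("V", "A", "H", "D")
           else c("V", "A", "H_mean", "D_mean", "NrS")
  max_size <- if (dataset_kind == "trees") 3 else 4
  specs <- list()
  for (sz in seq_len(max_size)) {
    for (subset in utils::combn(preds, sz, simplify = FALSE)) {
      for (fam in c("linear", "ln_linear", "power_sum")) {
        specs[[length(specs) + 1]] <- model_spec(response, subset, fam)
      }
    }
  }
  keys <- vapply(specs, function(s)
    paste(s$family, paste(s$predictors, collapse = ","), sep = "|"),
    character(1))
  specs[!duplicated(keys)]
}

#' Fit every candidate model of a zoo
#'
#' Fits each spec from [enumerate_models()]; fits that error or fail to
#' converge are kept with `converged = FALSE` and are excluded from
#' selection.
#'
#' @param data tree or stand table.
#' @param dataset_kind `"trees"` or `"stands"`.
#' @param response response name.
#' @return list of `allom_fit` objects.
#' @export
fit_zoo <- function(data, dataset_kind, response) {
  specs <- enumerate_models(dataset_kind, response)
  lapply(specs, function(sp) {
    tryCatch(fit_model(sp, data), error = function(e) {
      structure(list(spec = sp, coefficients = NULL, n = nrow(data),
                     RSS = NA_real_, RMSE = NA_real_,
                     k = .n_mean_params(sp) + 1L,
                     converged = FALSE, BIC = NA_real_, error = conditionMessage(e)),
                class = "allom_fit")
    })
  })
}

#' Select the best and the most parsimonious model
#'
#' The best model is the converged fit with the globally lowest BIC. The most
#' parsimonious model is the lowest-BIC fit among those using `v*` predictors,
#' where `v*` is the smallest predictor count whose best BIC comes within
#' `delta_bic` of the global minimum (default 10, the strong-evidence
#' threshold). Ties are broken by fewer parameters, then family order linear
#' < ln_linear < power_sum.
#'
#' @param fits list of `allom_fit` objects (e.g. from [fit_zoo()]).
#' @param delta_bic BIC ladder width for the parsimony rule.
#' @return list with elements `best` and `parsimonious` (both `allom_fit`).
#' @export
select_models <- function(fits, delta_bic = 10) {
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$n), fits)
  conv <- Filter(function(f) !is.na(f$BIC), conv)
  if (length(conv) == 0)
    stop("selection error: no converged fit", call. = FALSE)

  fam_rank <- c(linear = 1, ln_linear = 2, power_sum = 3)
  ord_key <- function(f) c(f$BIC, f$k, fam_rank[[f$spec$family]])
  pick <- function(lst) {
    keys <- t(vapply(lst, ord_key, numeric(3)))
    lst[[order(keys[, 1], keys[, 2], keys[, 3])[1]]]
  }

  best <- pick(conv)
  nvars <- vapply(conv, function(f) length(f$spec$predictors), integer(1))
  best_bic_by_v <- tapply(vapply(conv, function(f) f$BIC, numeric(1)),
                          nvars, min)
  v_star <- min(as.integer(names(best_bic_by_v))[
    best_bic_by_v <= best$BIC + delta_bic])
  parsimonious <- pick(conv[nvars == v_star])
  list(best = best, parsimonious = parsimonious)
}

#' Fit the combined volumetric model over pooled trees and stands
#'
#' Pooled ordinary least squares of total dry biomass on plant/stand volume:
#' the user-friendly simplification `BM ~ a + b x Vol` that can be driven by
#' remote-sensing volume alone.
#'
#' @param trees single-tree table with `V` and `total_dry`.
#' @param stands stand table with `volume_m3` (or `V`) and `total_dry`.
#' @return an `allom_fit` of family `linear`, response `total`, predictor `V`.
#' @export
fit_combined_volume_model <- function(trees, stands) {
  pool <- rbind(
    data.frame(V = trees[[.predictor_column("V", trees)]],
               total_dry = trees[[.response_column("total", trees)]]),
    data.frame(V = stands[[.predictor_column("V", stands)]],
               total_dry = stands[[.response_column("total", stands)]])
  )
  pool <- pool[stats::complete.cases(pool), ]
  if (nrow(pool) < 3)
    stop("domain error: fewer than 3 pooled observations", call. = FALSE)
  fit_model(model_spec("total", "V", "linear"), pool)
}

#' Best / most-parsimonious selection table for a set of responses
#'
#' Runs the full zoo and selection per response, mirroring the published
#' model tables: one row per response with both selected equations and their
#' RMSE.
#'
#' @param data tree or stand table (with any nutrient-total columns already
#'   appended, see [pool_totals()]).
#' @param dataset_kind `"trees"` or `"stands"`.
#' @param responses character vector of response names present in `data`.
#' @param delta_bic parsimony ladder width, see [select_models()].
#' @return data.frame with columns `response`, `parsimonious_equation`,
#'   `parsimonious_RMSE`, `best_equation`, `best_RMSE`, `delta_RMSE_pct`.
#' @export
selection_table <- function(data, dataset_kind, responses, delta_bic = 10) {
  rows <- lapply(responses, function(resp) {
    sel <- select_models(fit_zoo(data, dataset_kind, resp), delta_bic)
    data.frame(
      response = resp,
      parsimonious_equation = format_equation(sel$parsimonious),
      parsimonious_RMSE = sel$parsimonious$RMSE,
      best_equation = format_equation(sel$best),
      best_RMSE = sel$best$RMSE,
      delta_RMSE_pct = 100 * (sel$parsimonious$RMSE - sel$best$RMSE) /
        sel$best$RMSE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Serialise a fitted model to JSON
#'
#' @param fit an `allom_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(response = fit$spec$response,
              predictors = fit$spec$predictors,
              family = fit$spec$family,
              coefficients = as.list(fit$coefficients),
              n = fit$n, RSS = fit$RSS, RMSE = fit$RMSE, BIC = fit$BIC,
              converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
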