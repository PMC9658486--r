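#' Generate a synthetic tissue-chemistry table
#'
#' One row per tissue x sampling unit, drawn `Normal(mean, SE)` around the
#' configured chemistry table (default: the published tissue means and
#' standard errors, [reference_chemistry()]). Concentration draws (C, N, P)
#' that come out non-positive are resampled, never emitted; isotope signatures
#' may be negative. Stoichiometric ratios are recomputed from the drawn
#' concentrations, so `CN_ratio == C_pct / N_pct` holds exactly per row.
#'
#' @param config a [generator_config()]; uses `config$chemistry_means_ses`
#'   and `config$seed`.
#' @return data.frame with columns `unit`, `tissue`, `C_pct`, `N_pct`,
#'   `P_permil` (NA where unmeasured), `d13C`, `d15N`, `CN_ratio`, `NP_ratio`.
#' @export
generate_chemistry <- function(config) {
  validate_generator_config(config)
  tab <- config$chemistry_means_ses
  need <- c("unit", "tissue", "C_pct_mean", "C_pct_se", "N_pct_mean",
            "N_pct_se", "P_permil_mean", "P_permil_se", "d15N_mean",
            "d15N_se", "d13C_mean", "d13C_se")
  if (!all(need %in% names(tab)))
    stop("configuration error: chemistry_means_ses misses required columns",
         call. = FALSE)
  set.seed(config$seed + 2L)
  n <- nrow(tab)

  draw_pos <- function(mean, se) {
    out <- rep(NA_real_, length(mean))
    for (i in seq_along(mean)) {
      if (is.na(mean[i])) next
      x <- stats::rnorm(1, mean[i], se[i])
      while (x <= 0) x <- stats::rnorm(1, mean[i], se[i])
      out[i] <- x
    }
    out
  }
  C <- draw_pos(tab$C_pct_mean, tab$C_pct_se)
  N <- draw_pos(tab$N_pct_mean, tab$N_pct_se)
  P <- draw_pos(tab$P_permil_mean, tab$P_permil_se)
  draw_any <- function(mean, se) {
    out <- rep(NA_real_, length(mean))
    ok <- !is.na(mean)
    out[ok] <- stats::rnorm(sum(ok), mean[ok], se[ok])
    out
  }
  d15N <- draw_any(tab$d15N_mean, tab$d15N_se)
  d13C <- draw_any(tab$d13C_mean, tab$d13C_se)
  if (any(C >= 100, na.rm = TRUE) || any(N >= 100, na.rm = TRUE))
    stop("configuration error: concentration draw exceeded 100%", call. = FALSE)

  data.frame(unit = tab$unit, tissue = tab$tissue,
             C_pct = C, N_pct = N, P_permil = P,
             d13C = d13C, d15N = d15N,
             CN_ratio = C / N,
             NP_ratio = ifelse(is.na(P), NA_real_, (N * 10) / P),
             stringsAsFactors = FALSE)
}
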