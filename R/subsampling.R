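#' Monte-Carlo correlation curve for subsampled height observations
#'
#' Estimates how many height observations per plot are needed before the
#' plot-mean height predicts total biomass as well as the full point cloud
#' does. For each subsample size `n`: repeat `reps` times \{draw `n` heights
#' per plot without replacement, average them, correlate the plot means with
#' total dry biomass across plots (Pearson's r)\}; store the mean r. Sizes
#' are reported per 100 m2 by scaling with the plot area
#' (`n_per_100 = n * 100 / plot_area_m2`).
#'
#' @param clouds list of numeric vectors: per-plot height observations
#'   (m above the soil reference), e.g. grid cells or point-cloud z values.
#' @param biomass numeric vector of per-plot total dry mass (kg), same length
#'   as `clouds` (at least 3 plots).
#' @param n_max largest per-plot subsample size (default 400); sizes whose
#'   cloud is too small are skipped with a warning.
#' @param n_values explicit vector of subsample sizes (overrides `1:n_max`).
#' @param reps Monte-Carlo repetitions per size (default 10000, the
#'   full-scale setting; reduce for exploratory runs).
#' @param seed integer seed.
#' @param plot_area_m2 plot area used for the per-100 m2 scaling (default 25).
#' @return object of class `"subsampling_curve"`: data.frame fields
#'   `n_values` (per plot), `n_per_100`, `mean_r`, plus attributes `reps`,
#'   `seed`, `full_r` (Pearson r using full-cloud means).
#' @export
r_curve <- function(clouds, biomass, n_max = 400, n_values = NULL,
                    reps = 10000, seed = 1L, plot_area_m2 = 25) {
  if (!is.list(clouds) || length(clouds) < 3)
    stop("domain error: need at least 3 plots", call. = FALSE)
  if (length(biomass) != length(clouds))
    stop("domain error: biomass and clouds lengths differ", call. = FALSE)
  clouds <- lapply(clouds, function(z) z[is.finite(z)])
  sizes <- vapply(clouds, length, integer(1))
  if (any(sizes < 1)) stop("domain error: empty cloud", call. = FALSE)

  if (is.null(n_values)) n_values <- seq_len(n_max)
  n_values <- sort(unique(as.integer(n_values)))
  feasible <- n_values <= min(sizes)
  if (!all(feasible)) {
    warning("skipping subsample sizes larger than the smallest cloud (",
            min(sizes), " points)")
    n_values <- n_values[feasible]
  }
  if (length(n_values) == 0)
    stop("domain error: no feasible subsample size", call. = FALSE)

  set.seed(seed)
  npl <- length(clouds)
  mean_r <- numeric(length(n_values))
  for (j in seq_along(n_values)) {
    n <- n_values[j]
    rs <- numeric(reps)
    means <- numeric(npl)
    for (rep_i in seq_len(reps)) {
      for (p in seq_len(npl)) {
        cl <- clouds[[p]]
        means[p] <- mean(cl[sample.int(length(cl), n)])
      }
      rs[rep_i] <- stats::cor(means, biomass)
    }
    mean_r[j] <- mean(rs)
  }

  full_r <- stats::cor(vapply(clouds, mean, numeric(1)), biomass)
  structure(list(n_values = n_values,
                 n_per_100 = n_values * 100 / plot_area_m2,
                 mean_r = mean_r),
            reps = reps, seed = seed, full_r = full_r,
            plot_area_m2 = plot_area_m2,
            class = "subsampling_curve")
}

#' @export
print.subsampling_curve <- function(x, ...) {
  cat(sprintf("subsampling curve: %d sizes (%g..%g per plot), %d reps\n",
              length(x$n_values), min(x$n_values), max(x$n_values),
              attr(x, "reps")))
  cat(sprintf("  mean r: %.3f .. %.3f (full cloud: %.3f)\n",
              min(x$mean_r), max(x$mean_r), attr(x, "full_r")))
  invisible(x)
}

#' Minimum number of height observations per 100 m2
#'
#' Fits the segmented hinge regression of `mean_r` on the per-100 m2
#' subsample size and returns the breakpoint: the size beyond which further
#' height observations no longer improve the biomass correlation. A
#' degenerate segmented fit (breakpoint at the search boundary, e.g. a flat
#' curve) propagates a no-breakpoint flag.
#'
#' @param curve a [r_curve()] result with at least 10 points.
#' @return list with `n_min` (breakpoint rounded to the nearest integer, or
#'   `NA` when flagged), `psi` (unrounded), `flag` (`"ok"` or
#'   `"no_breakpoint"`), and the underlying `segmented_fit`.
#' @export
min_observations <- function(curve) {
  if (!inherits(curve, "subsampling_curve"))
    stop("domain error: not a subsampling_curve", call. = FALSE)
  if (length(curve$n_values) < 10)
    stop("domain error: need at least 10 curve points", call. = FALSE)
  fit <- fit_segmented(curve$n_per_100, curve$mean_r)
  if (fit$degenerate) {
    return(list(n_min = NA_integer_, psi = fit$psi, flag = "no_breakpoint",
                fit = fit))
  }
  list(n_min = as.integer(round(fit$psi)), psi = fit$psi, flag = "ok",
       fit = fit)
}

#' Write a subsampling curve as CSV
#'
#' @param curve a [r_curve()] result.
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(n_per_plot = curve$n_values,
                              n_per_100m2 = curve$n_per_100,
                              mean_r = curve$mean_r),
                   path, row.names = FALSE)
  invisible(path)
}
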