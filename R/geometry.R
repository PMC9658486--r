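#' Canopy area from two perpendicular canopy diameters
#'
#' The canopy is treated as a circle whose radius is the mean of the two
#' measured canopy radii: `A = pi * ((C1 + C2) / 4)^2`.
#'
#' @param C1 largest canopy diameter (m).
#' @param C2 canopy diameter perpendicular to `C1` (m); must satisfy
#'   `C1 >= C2 > 0`.
#' @return canopy area in m2. Vectorised.
#' @export
#' @examples
#' canopy_area(2, 2)  # pi
canopy_area <- function(C1, C2) {
  if (any(!is.finite(C1)) || any(!is.finite(C2)) || any(C1 <= 0) || any(C2 <= 0))
    stop("domain error: canopy diameters must be positive", call. = FALSE)
  if (any(C1 < C2))
    stop("domain error: C1 must be the largest diameter (C1 >= C2)",
         call. = FALSE)
  pi * ((C1 + C2) / 4)^2
}

#' Conic plant volume
#'
#' Plant volume is modelled as a cone over the canopy area: `V = A * H / 3`.
#'
#' @param A canopy area (m2), positive.
#' @param H total plant height (m), positive.
#' @return volume in m3. Vectorised.
#' @export
cone_volume <- function(A, H) {
  if (any(!is.finite(A)) || any(!is.finite(H)) || any(A <= 0) || any(H <= 0))
    stop("domain error: area and height must be positive", call. = FALSE)
  A * H / 3
}

#' Canopy height grid
#'
#' A regular grid of surface elevations over a plot, as produced by a
#' photogrammetric digital terrain model. `z` is stored with row 1 = northern
#' (top) row, matching the ESRI-ASCII convention. `NA` cells are nodata and
#' are ignored by all summaries.
#'
#' @param z numeric matrix of surface elevations (m).
#' @param cell_size grid resolution (m), positive.
#' @param plot_id identifier.
#' @param origin `(x, y)` of the lower-left corner (m).
#' @param z0 soil reference elevation (m), or `NA` if not yet set (see
#'   [soil_reference()]).
#' @return an object of class `"height_grid"`.
#' @export
height_grid <- function(z, cell_size, plot_id = "plot", origin = c(0, 0),
                        z0 = NA_real_) {
  z <- as.matrix(z)
  if (!is.numeric(z) || any(is.infinite(z)))
    stop("domain error: z must be finite numeric (NA = nodata)", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("domain error: cell_size must be a positive scalar", call. = FALSE)
  structure(list(plot_id = plot_id, origin = as.numeric(origin),
                 cell_size = cell_size, z = z, z0 = z0),
            class = "height_grid")
}

#' @export
print.height_grid <- function(x, ...) {
  cat(sprintf("height_grid '%s': %d x %d cells of %.3g m (%.4g m2)\n",
              x$plot_id, nrow(x$z), ncol(x$z), x$cell_size,
              sum(!is.na(x$z)) * x$cell_size^2))
  cat(sprintf("  z: [%.3g, %.3g] m, z0 = %s\n",
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE),
              ifelse(is.na(x$z0), "unset", format(x$z0))))
  invisible(x)
}

.grid_heights <- function(grid) {
  if (!inherits(grid, "height_grid"))
    stop("domain error: not a height_grid", call. = FALSE)
  if (is.na(grid$z0))
    stop("state error: soil reference z0 is unset; call soil_reference() first",
         call. = FALSE)
  h <- grid$z - grid$z0
  h[!is.na(h)]
}

#' Soil reference elevation from bare-ground cells
#'
#' The study sites are flat, so the soil reference is the mean surface
#' elevation over cells known to be bare of vegetation. A planar fit
#' (`method = "plane"`) is available for gently sloping sites.
#'
#' @param grid a [height_grid()].
#' @param bare_cells logical matrix of `dim(grid$z)`, or a two-column matrix
#'   of (row, col) indices, marking vegetation-free cells.
#' @param method `"mean"` (default) or `"plane"` (least-squares plane over the
#'   bare cells, evaluated at the grid centre).
#' @return the input grid with `z0` set.
#' @export
soil_reference <- function(grid, bare_cells, method = c("mean", "plane")) {
  method <- match.arg(method)
  if (!inherits(grid, "height_grid"))
    stop("domain error: not a height_grid", call. = FALSE)
  if (is.logical(bare_cells)) {
    if (!identical(dim(bare_cells), dim(grid$z)))
      stop("reference error: bare-cell mask dimensions do not match the grid",
           call. = FALSE)
    idx <- which(bare_cells, arr.ind = TRUE)
  } else {
    idx <- as.matrix(bare_cells)
  }
  if (nrow(idx) == 0)
    stop("reference error: empty bare-cell mask", call. = FALSE)
  zb <- grid$z[idx]
  keep <- !is.na(zb)
  if (!any(keep))
    stop("reference error: all bare cells are nodata", call. = FALSE)
  if (method == "mean") {
    grid$z0 <- mean(zb[keep])
  } else {
    xy <- idx[keep, , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, xy[, 1], xy[, 2]), zb[keep])
    ctr <- c(1, (nrow(grid$z) + 1) / 2, (ncol(grid$z) + 1) / 2)
    grid$z0 <- sum(fit$coefficients * ctr)
  }
  grid
}

#' Surface volume of a canopy height grid
#'
#' Sum over cells of `max(z - z0, 0) * cell_size^2`: the volume enclosed
#' between the canopy surface and the soil reference plane. Heights below the
#' reference are clamped to zero; nodata cells are skipped.
#'
#' @param grid a [height_grid()] with `z0` set.
#' @return volume in m3.
#' @export
surface_volume <- function(grid) {
  h <- .grid_heights(grid)
  sum(pmax(h, 0)) * grid$cell_size^2
}

#' Vegetation cover area above a height threshold
#'
#' Counts cells whose canopy height strictly exceeds `threshold` (default
#' 0.30 m, the operational cut-off separating vegetation from bare ground)
#' and converts the count to m2.
#'
#' @inheritParams surface_volume
#' @param threshold height threshold in metres, `>= 0`.
#' @return covered area in m2.
#' @export
cover_area <- function(grid, threshold = 0.30) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("domain error: threshold must be a non-negative scalar", call. = FALSE)
  h <- .grid_heights(grid)
  sum(h > threshold) * grid$cell_size^2
}

#' Mean canopy height
#'
#' Arithmetic mean of `z - z0` over all cells of a grid (or all points of a
#' point cloud). Negative heights (sensor noise over bare ground) are kept,
#' not clamped, so the estimate is unbiased on flat ground.
#'
#' @param x a [height_grid()] with `z0` set, or a numeric vector of point
#'   heights already expressed above the soil reference.
#' @return mean height in m.
#' @export
mean_height <- function(x) {
  if (inherits(x, "height_grid")) {
    h <- .grid_heights(x)
  } else {
    h <- x[!is.na(x)]
  }
  if (length(h) == 0)
    stop("domain error: no height observations", call. = FALSE)
  mean(h)
}

#' Rasterise an ideal cone onto a height grid
#'
#' Builds the canopy height grid of a single cone-shaped crown: apex height
#' `H` over a circular base of area `A`, sampled at cell centres. Used by the
#' synthetic-data generator and as a closed-form oracle in validation (grid
#' surface volume converges to `A*H/3`, grid mean height over the base disc
#' to `H/3`).
#'
#' @param A base area (m2).
#' @param H apex height (m).
#' @param cell_size grid resolution (m).
#' @param mask_outside if `TRUE`, cells outside the base disc are nodata
#'   (`NA`) instead of 0, so summaries refer to the disc only.
#' @return a [height_grid()] with `z0 = 0`.
#' @export
rasterize_cone <- function(A, H, cell_size, mask_outside = FALSE) {
  cone_volume(A, H)  # validates positivity
  r <- sqrt(A / pi)
  n <- ceiling(2 * r / cell_size)
  cc <- (seq_len(n) - 0.5) * cell_size - r   # cell-centre coords, cone at 0
  d <- sqrt(outer(cc^2, cc^2, "+"))
  z <- H * pmax(1 - d / r, 0)
  if (mask_outside) z[d > r] <- NA_real_
  height_grid(z, cell_size, plot_id = "cone", z0 = 0)
}
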