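#' Read and write xyz point clouds
#'
#' Whitespace-delimited text with three columns `x y z` in metres, no header —
#' the exchange format of photogrammetric point clouds.
#'
#' @param path file path.
#' @return `read_xyz`: a data.frame with columns `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  m <- matrix(scan(path, what = double(), quiet = TRUE), ncol = 3, byrow = TRUE)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
}

#' @rdname read_xyz
#' @param points data.frame (or matrix) with columns `x`, `y`, `z`.
#' @export
write_xyz <- function(points, path) {
  m <- as.data.frame(points)[, c("x", "y", "z")]
  utils::write.table(format(m, trim = TRUE, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a height grid to an xyz point cloud
#'
#' One point per non-nodata cell, at the cell centre, `z` as stored (surface
#' elevation, not height above `z0`).
#'
#' @param grid a [height_grid()].
#' @return data.frame with columns `x`, `y`, `z`.
#' @export
grid_to_points <- function(grid) {
  nr <- nrow(grid$z); nc <- ncol(grid$z)
  cs <- grid$cell_size
  # row 1 is the top (north) row
  x <- grid$origin[1] + (col(grid$z) - 0.5) * cs
  y <- grid$origin[2] + (nr - row(grid$z) + 0.5) * cs
  keep <- !is.na(grid$z)
  data.frame(x = x[keep], y = y[keep], z = grid$z[keep])
}

#' Read and write ESRI-ASCII-style height grids
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' elevations, first row = northernmost. Nodata cells become `NA`.
#'
#' @param path file path.
#' @param plot_id identifier attached to the grid.
#' @return `read_esri_ascii`: a [height_grid()] (with `z0` unset).
#' @export
read_esri_ascii <- function(path, plot_id = basename(path)) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys))
    stop("parse error: missing ESRI-ASCII header fields", call. = FALSE)
  body <- scan(path, what = double(), skip = 6, quiet = TRUE)
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  if (length(body) != nc * nr)
    stop("parse error: grid body does not match ncols*nrows", call. = FALSE)
  z <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if ("nodata_value" %in% keys) z[z == vals[["nodata_value"]]] <- NA_real_
  org <- c(ifelse("xllcorner" %in% keys, vals[["xllcorner"]], 0),
           ifelse("yllcorner" %in% keys, vals[["yllcorner"]], 0))
  height_grid(z, vals[["cellsize"]], plot_id = plot_id, origin = org)
}

#' @rdname read_esri_ascii
#' @param grid a [height_grid()].
#' @param nodata numeric value written for `NA` cells.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  z <- grid$z
  z[is.na(z)] <- nodata
  hdr <- c(paste("ncols", ncol(z)),
           paste("nrows", nrow(z)),
           paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
           paste("yllcorner", format(grid$origin[2], scientific = FALSE)),
           paste("cellsize", format(grid$cell_size, scientific = FALSE)),
           paste("NODATA_value", format(nodata, scientific = FALSE)))
  rows <- apply(z, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write generated tables as CSV
#'
#' UTF-8, "." decimal separator, column names as documented for
#' [generate_trees()], [generate_stands()] and [generate_chemistry()].
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
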