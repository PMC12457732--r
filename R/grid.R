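#' Define a regular longitude-latitude grid (WGS 84)
#'
#' All rasters in rangecast live on an `env_grid`: an equal-angle grid in
#' decimal degrees on the WGS 84 geographic coordinate system (EPSG:4326).
#' Cells are square in degrees; the grid is stored row-major with row 0 at
#' the northern edge and cell ids 0-based, so tests can pin down exact cell
#' arithmetic.
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param west,south,east,north Bounding box in decimal degrees,
#'   `west < east`, `south < north`, within \[-180, 180\] x \[-90, 90\].
#' @return An object of class `env_grid`.
#' @export
#' @examples
#' g <- env_grid(10, 10, west = -70, south = -10, east = -65, north = -5)
#' g$cell_size
env_grid <- function(n_rows, n_cols, west, south, east, north) {
  check_scalar(n_rows, "n_rows", 1); check_scalar(n_cols, "n_cols", 1)
  check_scalar(west, "west", -180, 180); check_scalar(east, "east", -180, 180)
  check_scalar(south, "south", -90, 90); check_scalar(north, "north", -90, 90)
  if (east <= west || north <= south) {
    abort("invalid extent: need west < east and south < north")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  csx <- (east - west) / n_cols
  csy <- (north - south) / n_rows
  if (abs(csx - csy) > 1e-9) {
    abort(sprintf("cells must be square in degrees (x size %.12g != y size %.12g)", csx, csy))
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         west = west, south = south, east = east, north = north,
         cell_size = csx, crs = "EPSG:4326"),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells, %.6g deg, extent [%g, %g] x [%g, %g] (%s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$west, x$east, x$south, x$north, x$crs))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$west - b$west) < tol && abs(a$south - b$south) < tol &&
    abs(a$east - b$east) < tol && abs(a$north - b$north) < tol
}

#' Map coordinates to 0-based row-major cell ids
#'
#' Cell membership uses half-open intervals `[west, east) x [south, north)`
#' per cell, so a point on a shared boundary belongs to exactly one cell
#' (the one to its east / north). Points outside the grid map to `NA`.
#'
#' @param grid An [env_grid()].
#' @param longitude,latitude Coordinate vectors in decimal degrees.
#' @return Integer vector of 0-based cell ids (`row * n_cols + col`, row 0
#'   at the north edge), `NA` for points outside the grid.
#' @export
cell_from_lonlat <- function(grid, longitude, latitude) {
  col <- floor((longitude - grid$west) / grid$cell_size)
  # floor() on (lat - south) makes the cell's own south edge inclusive,
  # matching the half-open convention; counting rows from the south edge
  # then flipping keeps the exact-boundary case in the correct cell.
  row_s <- floor((latitude - grid$south) / grid$cell_size)
  row <- grid$n_rows - 1 - row_s
  inside <- col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  out <- rep(NA_integer_, length(longitude))
  out[inside] <- as.integer(row[inside] * grid$n_cols + col[inside])
  out
}

#' Cell-center coordinates of 0-based cell ids
#'
#' @param grid An [env_grid()].
#' @param cell Integer vector of 0-based row-major cell ids.
#' @return A tibble with columns `cell`, `longitude`, `latitude`.
#' @export
cell_center <- function(grid, cell) {
  row <- cell %/% grid$n_cols
  col <- cell %% grid$n_cols
  tibble(
    cell = as.integer(cell),
    longitude = grid$west + (col + 0.5) * grid$cell_size,
    latitude = grid$north - (row + 0.5) * grid$cell_size
  )
}

# mean Earth radius giving the true surface area (authalic radius), km
.R_AUTHALIC_KM <- 6371.0072

#' Spherical cell area in square kilometres
#'
#' Computes the WGS 84 (EPSG:4326) pixel area accounting for Earth's
#' curvature: on the sphere of authalic radius R, a cell bounded by
#' latitudes \eqn{\phi_s, \phi_n} and spanning \eqn{\Delta\lambda} radians
#' of longitude has area
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\phi_n - \sin\phi_s).}
#' Area depends only on the cell's row (latitude band), not its column.
#'
#' @param grid An [env_grid()].
#' @param row 0-based row index vector (row 0 at the north edge).
#' @return Numeric vector of areas in km^2.
#' @export
#' @examples
#' g <- env_grid(360, 720, -180, -90, 180, 90) # global 0.5 degree grid
#' cell_area_km2(g, 179) # 0.5 x 0.5 deg cell just north of the equator
cell_area_km2 <- function(grid, row) {
  if (any(row < 0 | row >= grid$n_rows)) abort("row index outside grid")
  phi_n <- (grid$north - row * grid$cell_size) * pi / 180
  phi_s <- (grid$north - (row + 1) * grid$cell_size) * pi / 180
  dlam <- grid$cell_size * pi / 180
  .R_AUTHALIC_KM^2 * dlam * (sin(phi_n) - sin(phi_s))
}
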