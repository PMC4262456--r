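#' Build the standard analysis grid
#'
#' Constructs a regular lon/lat grid of square cells (default 0.25 degrees,
#' the resolution at which tracking, survey and satellite data are
#' standardized). Cells are half-open intervals `[west, east) x [south,
#' north)` so every point inside the bounding box belongs to exactly one
#' cell. Cell ids run row-major from the south-west corner.
#'
#' @param bbox Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees. Must span at least one cell in each direction and be
#'   alignable to `resolution`.
#' @param resolution Cell size in degrees (default 0.25).
#' @return An object of class `std_grid`: list with `bbox`, `resolution`,
#'   `nlon`, `nlat`, `n_cells`, cell-center coordinate vectors `lon`, `lat`.
#' @export
build_grid <- function(bbox, resolution = 0.25) {
  stopifnot(length(bbox) == 4)
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0")
  lon_min <- bbox[1]; lon_max <- bbox[2]
  lat_min <- bbox[3]; lat_max <- bbox[4]
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("degenerate bbox: zero or negative extent")
  nlon <- round((lon_max - lon_min) / resolution)
  nlat <- round((lat_max - lat_min) / resolution)
  if (abs(nlon * resolution - (lon_max - lon_min)) > 1e-8 ||
      abs(nlat * resolution - (lat_max - lat_min)) > 1e-8)
    stop("bbox extent is not a multiple of the resolution")
  g <- list(
    bbox = c(lon_min, lon_max, lat_min, lat_max),
    resolution = resolution,
    nlon = nlon, nlat = nlat, n_cells = nlon * nlat,
    lon = lon_min + (seq_len(nlon) - 0.5) * resolution,
    lat = lat_min + (seq_len(nlat) - 0.5) * resolution
  )
  class(g) <- "std_grid"
  g
}

#' @export
print.std_grid <- function(x, ...) {
  cat(sprintf("standard grid: %d x %d cells (%g deg), lon [%g, %g], lat [%g, %g]\n",
              x$nlon, x$nlat, x$resolution,
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Map points to grid cells
#'
#' Applies the half-open cell convention: a point on a shared edge belongs
#' to the cell whose west/south edge it lies on. Points outside the
#' bounding box map to `NA`.
#'
#' @param grid A `std_grid`.
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Integer cell ids (row-major from the south-west corner), `NA`
#'   for points outside the grid.
#' @export
cell_at <- function(grid, lon, lat) {
  ci <- floor((lon - grid$bbox[1]) / grid$resolution) + 1
  ri <- floor((lat - grid$bbox[3]) / grid$resolution) + 1
  bad <- ci < 1 | ci > grid$nlon | ri < 1 | ri > grid$nlat |
    is.na(lon) | is.na(lat)
  id <- (ri - 1L) * grid$nlon + ci
  id[bad] <- NA_integer_
  as.integer(id)
}

#' Cell-center coordinates
#'
#' @param grid A `std_grid`.
#' @param cells Optional integer cell ids; default all cells.
#' @return data.frame with `cell`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = seq_len(grid$n_cells)) {
  ri <- (cells - 1L) %/% grid$nlon + 1L
  ci <- (cells - 1L) %% grid$nlon + 1L
  data.frame(cell = cells, lon = grid$lon[ci], lat = grid$lat[ri])
}

#' Cell areas in square kilometres
#'
#' Spherical approximation: meridional extent is constant, zonal extent
#' shrinks with the cosine of the cell-center latitude (radius 6371 km).
#'
#' @inheritParams cell_centers
#' @return Numeric vector of areas (km^2).
#' @export
cell_area_km2 <- function(grid, cells = seq_len(grid$n_cells)) {
  km_per_deg <- 6371 * pi / 180
  cc <- cell_centers(grid, cells)
  dy <- grid$resolution * km_per_deg
  dx <- grid$resolution * km_per_deg * cos(cc$lat * pi / 180)
  dx * dy
}

## layer matrices are [nlat, nlon], row 1 = southernmost band
layer_matrix <- function(grid, values) {
  matrix(values, nrow = grid$nlat, ncol = grid$nlon, byrow = TRUE)
}

layer_values <- function(layer, cells) {
  nlon <- ncol(layer)
  ri <- (cells - 1L) %/% nlon + 1L
  ci <- (cells - 1L) %% nlon + 1L
  layer[cbind(ri, ci)]
}

#' Spatial gradient (slope magnitude) of a gridded layer
#'
#' Horn's 3x3 finite-difference stencil, the standard slope operator for
#' raster terrain analysis, with a per-row metric correction: the zonal
#' cell size in km shrinks with latitude, so the same one-cell step spans
#' fewer kilometres near the poles. Edge cells reuse their nearest
#' neighbours (replicate padding).
#'
#' @param layer Numeric matrix `[nlat, nlon]` on `grid` (row 1 = south).
#' @param grid A `std_grid`.
#' @return Matrix of the same shape: slope magnitude in layer units per km.
#' @export
gradient_layer <- function(layer, grid) {
  stopifnot(nrow(layer) == grid$nlat, ncol(layer) == grid$nlon)
  nr <- nrow(layer); nc <- ncol(layer)
  ## replicate-pad one ring
  p <- layer[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  zNW <- p[i + 1L, j - 1L]; zN <- p[i + 1L, j]; zNE <- p[i + 1L, j + 1L]
  zW  <- p[i, j - 1L];                         zE  <- p[i, j + 1L]
  zSW <- p[i - 1L, j - 1L]; zS <- p[i - 1L, j]; zSE <- p[i - 1L, j + 1L]
  km_per_deg <- 6371 * pi / 180
  dx_km <- grid$resolution * km_per_deg * cos(grid$lat * pi / 180)
  dy_km <- grid$resolution * km_per_deg
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * dx_km)
  dzdy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * dy_km)
  sqrt(dzdx^2 + dzdy^2)
}
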