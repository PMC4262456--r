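## Smooth random fields --------------------------------------------------
##
## Spatially autocorrelated fields are produced by low-pass filtering white
## noise with a separable Gaussian kernel (reflection padding), then
## re-standardizing to zero mean / unit sd. This gives the autocorrelation
## the habitat models assume without a full geostatistical simulator.

conv_reflect <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  n <- length(v)
  pad_l <- rev(v)[n - seq_len(half) + 1L]   # v[half:1]
  pad_r <- rev(v)[seq_len(half)]
  vp <- c(pad_l, v, pad_r)
  out <- as.numeric(stats::filter(vp, k, sides = 2))
  out[(half + 1L):(half + n)]
}

smooth_field <- function(nlat, nlon, sigma_cells = 2) {
  m <- matrix(rnorm(nlat * nlon), nlat, nlon)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  m <- apply(m, 2, conv_reflect, k = k)            # along latitude
  m <- t(apply(m, 1, conv_reflect, k = k))         # along longitude
  (m - mean(m)) / sd(m)
}

## Sum of Gaussian bumps (closed mesoscale anomalies) at random centers.
eddy_field <- function(grid, n_eddies, amp_cm, radius_deg) {
  lon <- matrix(grid$lon, grid$nlat, grid$nlon, byrow = TRUE)
  lat <- matrix(grid$lat, grid$nlat, grid$nlon)
  f <- matrix(0, grid$nlat, grid$nlon)
  for (e in seq_len(n_eddies)) {
    cx <- runif(1, grid$bbox[1] + radius_deg, grid$bbox[2] - radius_deg)
    cy <- runif(1, grid$bbox[3] + radius_deg, grid$bbox[4] - radius_deg)
    a <- sample(c(-1, 1), 1) * runif(1, 0.6, 1) * amp_cm
    f <- f + a * exp(-((lon - cx)^2 + (lat - cy)^2) / (2 * radius_deg^2))
  }
  f
}

#' Generate a synthetic seascape
#'
#' Builds monthly environmental layers on the standard grid with the
#' structure the habitat models assume: a time-invariant bathymetry with a
#' shallow shelf margin and a deep interior, a sea surface temperature
#' field with a monotone latitudinal trend plus smooth anomalies, a sea
#' level anomaly field containing closed mesoscale eddies, and a strictly
#' positive (log-normal) chlorophyll-a field. All dynamic layers are
#' indexed by (month, year) and differ between periods; everything is
#' deterministic given `seed`.
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in degrees; must
#'   span at least 8 x 8 cells at `resolution`.
#' @param years Integer vector of years.
#' @param months Integer vector of months, subset of September-December
#'   (9:12), the breeding window the analysis targets.
#' @param seed Integer seed (required for reproducibility; may be `NULL`).
#' @param resolution Grid resolution in degrees (default 0.25).
#' @param colony Colony location `c(lon, lat)`; default the grid center.
#' @param n_eddies Number of mesoscale anomalies per monthly SLA layer
#'   (default 3, at least 2).
#' @return Object of class `seascape`: list with `grid` (a [build_grid()]
#'   `std_grid`), `colony`, `years`, `months`, static matrix `bathy` (m,
#'   negative at sea) and `dynamic[[key]]` with matrices `Chloa` (mg m-3),
#'   `SST` (deg C), `SLA` (cm) where `key` is `"YYYY-MM"`.
#' @export
generate_seascape <- function(bbox, years, months = 9:12, seed = NULL,
                              resolution = 0.25, colony = NULL,
                              n_eddies = 3) {
  grid <- build_grid(bbox, resolution)
  if (grid$nlon < 8 || grid$nlat < 8)
    stop("bbox must span at least 8 x 8 cells at the given resolution")
  if (!all(months %in% 9:12))
    stop("months must lie in the September-December window (9:12)")
  if (n_eddies < 2) stop("n_eddies must be >= 2")
  if (is.null(colony))
    colony <- c(mean(grid$bbox[1:2]), mean(grid$bbox[3:4]))

  with_seed(seed, {
    nlat <- grid$nlat; nlon <- grid$nlon
    ## bathymetry: shallow shelf along the western margin, deep interior
    shelf <- matrix(rep(seq_len(nlon), each = nlat), nlat, nlon)
    shelf_km <- (shelf - 1) * resolution * 111
    depth <- -(40 + 3960 * (1 - exp(-shelf_km / 150)))
    bathy <- depth + 150 * smooth_field(nlat, nlon, 2)
    bathy <- pmin(bathy, -5)

    lat_m <- matrix(grid$lat, nlat, nlon)
    dynamic <- list()
    for (yr in sort(unique(years))) {
      for (mo in sort(unique(months))) {
        key <- sprintf("%d-%02d", yr, mo)
        sst <- 29 - 0.45 * (lat_m - grid$bbox[3]) +
          0.3 * (mo - 10) + 0.7 * smooth_field(nlat, nlon, 2)
        sla <- eddy_field(grid, n_eddies, amp_cm = 22, radius_deg = 0.9) +
          2.5 * smooth_field(nlat, nlon, 3)
        chloa <- 0.15 * exp(0.7 * smooth_field(nlat, nlon, 2))
        dynamic[[key]] <- list(Chloa = chloa, SST = sst, SLA = sla)
      }
    }
    ss <- list(grid = grid, colony = colony,
               years = sort(unique(years)), months = sort(unique(months)),
               bathy = bathy, dynamic = dynamic)
    class(ss) <- "seascape"
    ss
  })
}

#' @export
print.seascape <- function(x, ...) {
  cat(sprintf("seascape: %d x %d cells, %d monthly layer sets (%s), colony (%g, %g)\n",
              x$grid$nlon, x$grid$nlat, length(x$dynamic),
              paste(range(names(x$dynamic)), collapse = " .. "),
              x$colony[1], x$colony[2]))
  invisible(x)
}

seascape_key <- function(year, month) sprintf("%d-%02d", year, month)

#' Extract one environmental layer
#'
#' @param seascape A `seascape`.
#' @param var One of `"Chloa"`, `"SST"`, `"SLA"`, `"Bathy"`.
#' @param month,year Period for dynamic layers (ignored for `Bathy`).
#' @return Numeric matrix `[nlat, nlon]`.
#' @export
seascape_layer <- function(seascape, var, month = NULL, year = NULL) {
  if (var == "Bathy") return(seascape$bathy)
  key <- seascape_key(year, month)
  lay <- seascape$dynamic[[key]]
  if (is.null(lay)) stop("no layer set for period ", key)
  if (is.null(lay[[var]])) stop("unknown seascape variable: ", var)
  lay[[var]]
}

#' Full covariate table for one period
#'
#' Computes, for every grid cell, the nine candidate model covariates:
#' the four base layers, their spatial gradients ([gradient_layer()]) and
#' the great-circle distance to the colony (`DCol`, km).
#'
#' @param seascape A `seascape`.
#' @param month,year Period.
#' @return data.frame with `cell`, `lon`, `lat` and covariate columns
#'   `Chloa, SST, SLA, Bathy, DCol, Chloa_grad, SST_grad, SLA_grad,
#'   Bathy_grad`.
#' @export
seascape_covariates <- function(seascape, month, year) {
  grid <- seascape$grid
  cc <- cell_centers(grid)
  out <- cc
  for (v in c("Chloa", "SST", "SLA", "Bathy")) {
    lay <- seascape_layer(seascape, v, month, year)
    out[[v]] <- layer_values(lay, cc$cell)
    out[[paste0(v, "_grad")]] <- layer_values(gradient_layer(lay, grid), cc$cell)
  }
  out$DCol <- gc_dist_km(cc$lon, cc$lat, seascape$colony[1], seascape$colony[2])
  out[, c("cell", "lon", "lat", "Chloa", "SST", "SLA", "Bathy", "DCol",
          "Chloa_grad", "SST_grad", "SLA_grad", "Bathy_grad")]
}

covariate_names <- function() {
  c("Chloa", "SST", "SLA", "Bathy", "DCol",
    "Chloa_grad", "SST_grad", "SLA_grad", "Bathy_grad")
}

## Pooled normalization constants over all periods and cells; used by the
## simulators so that "truth" coefficients are on the standardized scale.
seascape_norm_constants <- function(seascape) {
  tabs <- lapply(names(seascape$dynamic), function(key) {
    yr <- as.integer(substr(key, 1, 4)); mo <- as.integer(substr(key, 6, 7))
    seascape_covariates(seascape, mo, yr)
  })
  all <- do.call(rbind, tabs)
  vars <- covariate_names()
  list(mean = vapply(all[vars], mean, 0), sd = vapply(all[vars], sd, 0))
}
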