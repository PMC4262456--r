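#' Per-trip presence cells from occupancy time
#'
#' Allocates each inter-fix interval of a trip to the grid cell containing
#' the interval midpoint and accumulates time spent per cell; every cell
#' with positive occupancy time is a presence cell for that trip. The
#' month/year of a trip is taken at its temporal midpoint so contemporaneous
#' covariates can be attached.
#'
#' @param trips Trajectory with `trip` labels (from [split_trips()]);
#'   rows with `NA` trip (at the colony) are ignored.
#' @param grid A `std_grid`.
#' @return data.frame with `trip`, `id`, `status`, `cell`, `time_h`,
#'   `month`, `year`.
#' @export
tracks_to_presence <- function(trips, grid) {
  if (!"trip" %in% names(trips)) stop("run split_trips() first: no trip column")
  d <- trips[!is.na(trips$trip), , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(trip = character(), id = character(), status = character(),
                      cell = integer(), time_h = numeric(),
                      month = integer(), year = integer()))
  }
  out <- lapply(split(d, d$trip, drop = TRUE), function(tr) {
    n <- nrow(tr)
    mid_t <- tr$timestamp[1] + (as.numeric(tr$timestamp[n]) -
                                as.numeric(tr$timestamp[1])) / 2
    mo <- as.integer(format(mid_t, "%m")); yr <- as.integer(format(mid_t, "%Y"))
    if (n == 1) {
      cells <- cell_at(grid, tr$lon, tr$lat)
      occ <- setNames(0, cells)  # single fix: presence with zero dwell
      occ[] <- .Machine$double.eps
    } else {
      mlon <- (tr$lon[-n] + tr$lon[-1]) / 2
      mlat <- (tr$lat[-n] + tr$lat[-1]) / 2
      dt_h <- diff(as.numeric(tr$timestamp)) / 3600
      cells <- cell_at(grid, mlon, mlat)
      ok <- !is.na(cells)
      occ <- tapply(dt_h[ok], cells[ok], sum)
    }
    if (!length(occ)) return(NULL)
    data.frame(trip = tr$trip[1], id = tr$id[1],
               status = tr$status[1],
               cell = as.integer(names(occ)), time_h = as.numeric(occ),
               month = mo, year = yr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

#' Generate per-trip pseudo-absences
#'
#' Tracking data carry presences only; for each trip an equal number of
#' pseudo-absence cells is drawn uniformly without replacement from the
#' cells within `limit_km` of the colony (the mean maximum range of
#' breeding birds, default 1000 km) that the bird did not cross on that
#' trip. If the eligible pool is smaller than the presence count the whole
#' pool is used, with a warning.
#'
#' @param presences Output of [tracks_to_presence()].
#' @param grid A `std_grid`.
#' @param colony `c(lon, lat)`.
#' @param limit_km Distance limit from the colony (default 1000).
#' @param seed Integer seed.
#' @return data.frame `trip`, `id`, `status`, `cell`, `month`, `year`,
#'   `response = 0`.
#' @export
generate_pseudo_absences <- function(presences, grid, colony,
                                     limit_km = 1000, seed = NULL) {
  stopifnot(limit_km > 0)
  cc <- cell_centers(grid)
  dcol <- gc_dist_km(cc$lon, cc$lat, colony[1], colony[2])
  in_range <- cc$cell[dcol <= limit_km]
  with_seed(seed, {
    out <- lapply(split(presences, presences$trip, drop = TRUE), function(pr) {
      pool <- setdiff(in_range, pr$cell)
      n <- nrow(pr)
      if (length(pool) < n) {
        warning("trip ", pr$trip[1], ": eligible pool (", length(pool),
                ") smaller than presence count (", n, "); using entire pool")
        take <- pool
      } else {
        take <- sample(pool, n)
      }
      if (!length(take)) return(NULL)
      data.frame(trip = pr$trip[1], id = pr$id[1], status = pr$status[1],
                 cell = take, month = pr$month[1], year = pr$year[1],
                 response = 0L, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(res) <- NULL
    res
  })
}

#' Presence/absence rows and cell-level occupancy from tracking data
#'
#' Convenience wrapper combining [tracks_to_presence()] (response 1) with
#' [generate_pseudo_absences()] (response 0) into one occurrence table
#' keyed by trip.
#'
#' @inheritParams generate_pseudo_absences
#' @return data.frame with `cell`, `month`, `year`, `group` (trip id),
#'   `response`, `source = "tracking"`.
#' @export
tracking_occurrence <- function(presences, grid, colony, limit_km = 1000,
                                seed = NULL) {
  pa <- generate_pseudo_absences(presences, grid, colony, limit_km, seed)
  pres <- data.frame(trip = presences$trip, id = presences$id,
                     status = presences$status, cell = presences$cell,
                     month = presences$month, year = presences$year,
                     response = 1L, stringsAsFactors = FALSE)
  occ <- rbind(pres, pa)
  data.frame(cell = occ$cell, month = occ$month, year = occ$year,
             group = occ$trip, status = occ$status, response = occ$response,
             source = "tracking", stringsAsFactors = FALSE)
}

#' Grid-aggregated occurrence and density from a strip-transect survey
#'
#' Aggregates survey bins over the standard grid by (cell, month, year,
#' campaign): density is total count over total effort area (individuals
#' per km^2) and the binary response records whether at least one
#' individual was seen. Surveyed cells with zero counts are absences;
#' unsurveyed cells do not appear.
#'
#' @param survey Survey table with `campaign`, `year`, `month`, `lon`,
#'   `lat`, `effort_km2` and a `count_<taxon>` column.
#' @param grid A `std_grid`.
#' @param taxon Taxon name (selects `count_<taxon>`).
#' @param source Label stored in the `source` column (default "vessel").
#' @return list with `rows` (data.frame `cell`, `month`, `year`, `group`
#'   = campaign, `response`, `density`, `source`) and `density_layers`
#'   (list of `[nlat, nlon]` matrices keyed `"YYYY-MM"`, `NA` where
#'   unsurveyed).
#' @export
surveys_to_occurrence <- function(survey, grid, taxon, source = "vessel") {
  cname <- paste0("count_", taxon)
  if (!cname %in% names(survey)) stop("no count column for taxon ", taxon)
  if (any(survey$effort_km2 <= 0)) stop("zero or negative effort in surveyed bin")
  d <- survey
  d$cell <- cell_at(grid, d$lon, d$lat)
  d <- d[!is.na(d$cell), , drop = FALSE]
  agg <- aggregate(cbind(count = d[[cname]], effort = d$effort_km2),
                   by = list(cell = d$cell, month = d$month, year = d$year,
                             group = d$campaign),
                   FUN = sum)
  if (any(agg$effort <= 0)) stop("zero total effort in a surveyed cell")
  rows <- data.frame(cell = agg$cell, month = agg$month, year = agg$year,
                     group = agg$group,
                     response = as.integer(agg$count >= 1),
                     density = agg$count / agg$effort,
                     source = source, stringsAsFactors = FALSE)
  layers <- list()
  for (key in unique(seascape_key(rows$year, rows$month))) {
    sel <- seascape_key(rows$year, rows$month) == key
    sub <- rows[sel, ]
    dens <- tapply(sub$density, sub$cell, mean)
    layers[[key]] <- layer_from_cells(grid, as.integer(names(dens)),
                                      as.numeric(dens))
  }
  list(rows = rows, density_layers = layers)
}

#' Attach contemporaneous environmental covariates
#'
#' Reads, for each occurrence row, the covariates of the matching monthly
#' layer at the row's cell center (plus `DCol`, the great-circle distance
#' from the cell center to the colony). Rows with any missing covariate
#' (e.g. cloud-masked chlorophyll) are dropped, with a message reporting
#' the count.
#'
#' @param rows Occurrence rows with `cell`, `month`, `year`.
#' @param seascape A `seascape` providing the layers.
#' @param colony `c(lon, lat)`; defaults to the seascape colony.
#' @return The rows with the nine covariate columns appended.
#' @export
attach_covariates <- function(rows, seascape, colony = seascape$colony) {
  keys <- unique(seascape_key(rows$year, rows$month))
  missing_k <- setdiff(keys, names(seascape$dynamic))
  if (length(missing_k))
    stop("no environmental layer for period(s): ", paste(missing_k, collapse = ", "))
  vars <- covariate_names()
  for (v in vars) rows[[v]] <- NA_real_
  for (key in keys) {
    sel <- seascape_key(rows$year, rows$month) == key
    yr <- rows$year[sel][1]; mo <- rows$month[sel][1]
    cov <- seascape_covariates(seascape, mo, yr)
    if (!identical(colony, seascape$colony)) {
      cov$DCol <- gc_dist_km(cov$lon, cov$lat, colony[1], colony[2])
    }
    for (v in vars) rows[[v]][sel] <- cov[[v]][rows$cell[sel]]
  }
  ok <- complete.cases(rows[vars])
  if (any(!ok))
    message(sum(!ok), " row(s) dropped for missing covariates")
  res <- rows[ok, , drop = FALSE]
  rownames(res) <- NULL
  res
}
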