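## Trajectory tables are plain data.frames with columns id, timestamp
## (POSIXct), lon, lat and optionally device / trip / status. All
## operations work per animal and return the same layout.

check_trajectory <- function(traj) {
  need <- c("id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop("trajectory lacks column(s): ", paste(miss, collapse = ", "))
  if (any(traj$lon < -180 | traj$lon > 180, na.rm = TRUE) ||
      any(traj$lat < -90 | traj$lat > 90, na.rm = TRUE))
    stop("coordinates outside lon [-180,180] / lat [-90,90]")
  for (id in unique(traj$id)) {
    tt <- as.numeric(traj$timestamp[traj$id == id])
    if (any(diff(tt) <= 0))
      stop("timestamps not strictly increasing for animal ", id)
  }
  invisible(traj)
}

segment_speeds_kmh <- function(d) {
  n <- nrow(d)
  if (n < 2) return(numeric(0))
  dist <- gc_dist_km(d$lon[-n], d$lat[-n], d$lon[-1], d$lat[-1])
  dt_h <- diff(as.numeric(d$timestamp)) / 3600
  dist / dt_h
}

#' Iterative forward/backward speed filter
#'
#' Removes unrealistic positions (ARGOS location errors) until no
#' consecutive pair of retained fixes implies a great-circle speed above
#' `vmax_kmh`. At each iteration the positions adjacent to a violating
#' segment are scored by their combined backward + forward speed and the
#' worst one is removed (the first such on ties); the first fix of a
#' trajectory is never removed. The result is idempotent: filtering a
#' filtered trajectory changes nothing.
#'
#' @param traj Trajectory data.frame (`id`, `timestamp`, `lon`, `lat`, ...).
#' @param vmax_kmh Speed threshold in km/h; default 65, the maximum
#'   plausible sustained flight speed for large seabirds.
#' @return The filtered trajectory (same columns, fewer rows).
#' @export
speed_filter <- function(traj, vmax_kmh = 65) {
  stopifnot(vmax_kmh > 0)
  check_trajectory(traj)
  out <- lapply(split(traj, traj$id, drop = TRUE), function(d) {
    if (nrow(d) < 2) return(d)
    keep <- seq_len(nrow(d))
    repeat {
      if (length(keep) < 2) break
      sp <- segment_speeds_kmh(d[keep, ])
      viol <- which(sp > vmax_kmh)
      if (!length(viol)) break
      cand <- sort(unique(c(viol, viol + 1L)))
      cand <- cand[cand != 1L]          # never remove the first fix
      if (!length(cand)) break
      comb <- vapply(cand, function(i) {
        back <- if (i > 1L) sp[i - 1L] else 0
        fwd <- if (i <= length(sp)) sp[i] else 0
        back + fwd
      }, 0)
      keep <- keep[-cand[which.max(comb)]]
    }
    d[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a trajectory into central-place foraging trips
#'
#' A trip is a maximal run of positions outside `colony_radius_km` of the
#' colony, bounded by colony visits. Trailing positions after the last
#' colony return are labelled `non-breeding` (the bird has abandoned
#' central-place foraging); every other trip is `breeding`. Positions at
#' the colony get `NA` trip labels.
#'
#' @param traj Trajectory data.frame.
#' @param colony `c(lon, lat)` of the colony.
#' @param colony_radius_km Radius defining "at the colony" (default 5).
#' @return The trajectory with added columns `trip` (e.g. `"A01_T01"`,
#'   `NA` at the colony) and `status` (`"breeding"`/`"non-breeding"`).
#' @export
split_trips <- function(traj, colony, colony_radius_km = 5) {
  if (missing(colony) || length(colony) != 2) stop("colony c(lon, lat) required")
  check_trajectory(traj)
  out <- lapply(split(traj, traj$id, drop = TRUE), function(d) {
    at_col <- gc_dist_km(d$lon, d$lat, colony[1], colony[2]) <= colony_radius_km
    d$trip <- NA_character_
    d$status <- NA_character_
    if (all(at_col)) return(d)
    r <- rle(!at_col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    last_col <- if (any(at_col)) max(which(at_col)) else 0L
    k <- 0L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      k <- k + 1L
      rows <- starts[j]:ends[j]
      d$trip[rows] <- sprintf("%s_T%02d", d$id[1], k)
      d$status[rows] <- if (starts[j] > last_col) "non-breeding" else "breeding"
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resample a trajectory to a coarser mean cadence
#'
#' Randomly thins fixes so the expected mean inter-fix gap matches
#' `target_interval_h` (default 1.57 h, the mean ARGOS PTT cadence),
#' making dense GPS tracks comparable with ARGOS tracks. The first fix of
#' each animal is always kept and order is preserved. Trajectories already
#' sparser than the target are returned unchanged with a warning.
#'
#' @param traj Trajectory data.frame.
#' @param target_interval_h Target mean gap in hours (default 1.57).
#' @param seed Integer seed for the random subsample.
#' @return Thinned trajectory.
#' @export
resample_track <- function(traj, target_interval_h = 1.57, seed = NULL) {
  stopifnot(target_interval_h > 0)
  check_trajectory(traj)
  with_seed(seed, {
    out <- lapply(split(traj, traj$id, drop = TRUE), function(d) {
      if (nrow(d) < 2) return(d)
      native <- mean(diff(as.numeric(d$timestamp))) / 3600
      if (native >= target_interval_h) {
        warning("trajectory ", d$id[1], " is already sparser than the target; unchanged")
        return(d)
      }
      p <- native / target_interval_h
      keep <- c(TRUE, runif(nrow(d) - 1) < p)
      d[keep, , drop = FALSE]
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Kernel utilization distribution
#'
#' Bivariate Gaussian kernel density of positions evaluated at the cell
#' centers of a grid and normalized so that density times cell area (in
#' squared degrees) integrates to one. The smoothing parameter `h` is the
#' kernel standard deviation in degrees on the lon/lat plane.
#'
#' @param positions data.frame with `lon`, `lat` (>= 1 row).
#' @param grid A `std_grid`.
#' @param h Smoothing parameter in degrees (default 0.5).
#' @return Object of class `kernel_ud`: list with `grid`, `h`, `density`
#'   matrix `[nlat, nlon]`.
#' @export
kernel_ud <- function(positions, grid, h = 0.5) {
  if (NROW(positions) < 1) stop("empty position set")
  stopifnot(h > 0)
  L <- dnorm(outer(grid$lat, positions$lat, "-"), sd = h)
  M <- dnorm(outer(grid$lon, positions$lon, "-"), sd = h)
  dens <- L %*% t(M) / NROW(positions)
  mass <- sum(dens) * grid$resolution^2
  if (mass <= 0) stop("all positions lie far outside the grid")
  structure(list(grid = grid, h = h, density = dens / mass),
            class = "kernel_ud")
}

#' Highest-density contour masks of a utilization distribution
#'
#' The level-L mask is the smallest set of highest-density cells whose
#' cumulative probability mass reaches L percent; masks are nested across
#' levels by construction (ties broken by cell id).
#'
#' @param ud A [kernel_ud()] object.
#' @param levels Percent levels (default `c(25, 50, 75, 95)`).
#' @return Named list of logical matrices `[nlat, nlon]`, one per level.
#' @export
ud_contours <- function(ud, levels = c(25, 50, 75, 95)) {
  stopifnot(all(levels > 0 & levels < 100))
  dens <- ud$density
  area <- ud$grid$resolution^2
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord] * area)
  masks <- lapply(levels, function(L) {
    n_in <- which(cum >= L / 100)[1]
    if (is.na(n_in)) n_in <- length(ord)
    m <- matrix(FALSE, nrow(dens), ncol(dens))
    m[ord[seq_len(n_in)]] <- TRUE
    m
  })
  names(masks) <- as.character(levels)
  masks
}
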