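#' Ground-truth occupancy coefficients for simulation
#'
#' Bundles the true coefficient vector (on standardized covariates), the
#' group-level random-intercept standard deviation and the simulation
#' seed, so recovery tests can compare fitted models against a known
#' generating process.
#'
#' @param coef Named numeric vector: must contain `INT` (intercept) and
#'   may contain any of the seascape covariates (`Chloa`, `SST`, `SLA`,
#'   `Bathy`, `DCol`, `*_grad`). Coefficients act on z-scored covariates.
#' @param sigma Standard deviation of the Normal(0, sigma) random
#'   intercept (campaign or individual); default 0.
#' @param seed Optional integer recorded for provenance.
#' @return Object of class `truth_record`.
#' @export
truth_record <- function(coef, sigma = 0, seed = NULL) {
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  if (!"INT" %in% names(coef)) stop("coef must contain an 'INT' intercept")
  vars <- setdiff(names(coef), "INT")
  bad <- setdiff(vars, covariate_names())
  if (length(bad))
    stop("unknown covariate(s) in truth: ", paste(bad, collapse = ", "))
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(coef = coef, sigma = sigma, seed = seed),
            class = "truth_record")
}

#' Write / read a truth record as plain-text key-value pairs
#'
#' @param truth A `truth_record`.
#' @param path File path.
#' @return `truth_read` returns a `truth_record`.
#' @export
truth_write <- function(truth, path) {
  lines <- c(
    sprintf("coef.%s = %.17g", names(truth$coef), truth$coef),
    sprintf("sigma = %.17g", truth$sigma),
    if (!is.null(truth$seed)) sprintf("seed = %d", as.integer(truth$seed))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname truth_write
#' @export
truth_read <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  is_coef <- startsWith(keys, "coef.")
  coef <- setNames(vals[is_coef], sub("^coef\\.", "", keys[is_coef]))
  truth_record(coef,
               sigma = if ("sigma" %in% keys) vals[keys == "sigma"] else 0,
               seed = if ("seed" %in% keys) vals[keys == "seed"] else NULL)
}

## Linear predictor of a truth record on an (already z-scored) covariate
## data.frame; covariates absent from the truth contribute nothing.
truth_lp <- function(truth, zcov) {
  vars <- setdiff(names(truth$coef), "INT")
  lp <- rep(truth$coef[["INT"]], nrow(zcov))
  for (v in vars) lp <- lp + truth$coef[[v]] * zcov[[v]]
  lp
}

## Per-period suitability lookup tables for the movement simulator:
## plogis(truth linear predictor) per cell, covariates standardized with
## pooled seascape constants.
suitability_tables <- function(seascape, truth) {
  vars <- setdiff(names(truth$coef), "INT")
  nc <- seascape_norm_constants(seascape)
  out <- list()
  for (key in names(seascape$dynamic)) {
    yr <- as.integer(substr(key, 1, 4)); mo <- as.integer(substr(key, 6, 7))
    cov <- seascape_covariates(seascape, mo, yr)
    lp <- rep(truth$coef[["INT"]], nrow(cov))
    for (v in vars) lp <- lp + truth$coef[[v]] *
      (cov[[v]] - nc$mean[[v]]) / nc$sd[[v]]
    out[[key]] <- plogis(lp)
  }
  out
}

#' Simulate central-place-forager tracks
#'
#' Discrete-time biased correlated random walk from a colony with
#' step selection: candidate steps follow a persistent heading with a
#' homeward bias that grows with distance, and the realized step is drawn
#' among candidates with probability proportional to the inverse-logit of
#' the true occupancy coefficients at each destination cell. Animals perform
#' repeated trips, returning to the colony between them; all true
#' positions stay within `max_range_km` of the colony. Timestamps are
#' irregular (truncated gamma gaps with mean `cadence_h`, the mean ARGOS
#' PTT cadence by default). A fraction `outlier_rate` of interior
#' positions is displaced far enough that the implied speed to both
#' neighbours exceeds 65 km/h, to exercise the speed filter.
#'
#' @param seascape A [generate_seascape()] seascape.
#' @param truth A [truth_record()]; its covariates must exist in the
#'   seascape.
#' @param n_animals Number of animals.
#' @param cadence_h Mean inter-fix gap in hours (default 1.57).
#' @param max_range_km Maximum range from the colony in km (default 1000).
#' @param outlier_rate Fraction of positions displaced as ARGOS-like
#'   outliers (default 0).
#' @param seed Integer seed.
#' @param n_steps Fixes per animal (default 300).
#' @param colony_radius_km Distance at which a returning animal is
#'   considered back at the colony (default 5).
#' @return data.frame with columns `id`, `timestamp` (POSIXct UTC), `lon`,
#'   `lat`, `device` ("PTT").
#' @export
simulate_tracks <- function(seascape, truth, n_animals, cadence_h = 1.57,
                            max_range_km = 1000, outlier_rate = 0,
                            seed = NULL, n_steps = 300,
                            colony_radius_km = 5) {
  stopifnot(cadence_h > 0, n_animals >= 1, outlier_rate >= 0, outlier_rate < 1)
  vars <- setdiff(names(truth$coef), "INT")
  missing_v <- setdiff(vars, covariate_names())
  if (length(missing_v))
    stop("truth covariate(s) missing from seascape: ",
         paste(missing_v, collapse = ", "))
  with_seed(seed, {
    suit <- suitability_tables(seascape, truth)
    keys <- names(seascape$dynamic)
    grid <- seascape$grid
    colony <- seascape$colony
    cc <- cell_centers(grid)
    cell_dcol <- gc_dist_km(cc$lon, cc$lat, colony[1], colony[2])
    reachable <- which(cell_dcol <= 0.85 * max_range_km)
    ## memory-directed trips: foraging destinations are drawn with
    ## probability proportional to suitability among reachable cells
    pick_target <- function(key) {
      w <- suit[[key]][reachable]
      reachable[sample.int(length(reachable), 1, prob = w)]
    }
    t0 <- as.POSIXct(sprintf("%d-%02d-01 00:00:00",
                             seascape$years[1], seascape$months[1]),
                     tz = "UTC")
    res <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      lon <- colony[1]; lat <- colony[2]
      heading <- runif(1, 0, 360)
      ## trips have a commute-forage-return structure: a persistent
      ## outbound leg, an area-restricted-search phase where habitat
      ## selection dominates, then a directed return to the colony
      phase <- "out"
      forage_target <- sample(25:50, 1)
      steps_in_phase <- 0L
      tm <- t0 + runif(1, 0, 3600)
      goal <- NULL
      out <- matrix(NA_real_, n_steps, 3)  # time, lon, lat
      for (s in seq_len(n_steps)) {
        gap <- min(max(rgamma(1, shape = 4, scale = cadence_h / 4),
                       0.2 * cadence_h), 4 * cadence_h)
        tm <- tm + gap * 3600
        mo <- as.integer(format(tm, "%m")); yr <- as.integer(format(tm, "%Y"))
        key <- seascape_key(yr, mo)
        if (!key %in% keys) key <- keys[length(keys)]
        dcol <- gc_dist_km(lon, lat, colony[1], colony[2])
        if (phase == "return" && dcol <= colony_radius_km) {
          lon <- colony[1]; lat <- colony[2]
          phase <- "out"
          forage_target <- sample(25:50, 1)
          steps_in_phase <- 0L
          goal <- NULL
          out[s, ] <- c(as.numeric(tm), lon, lat)
          next
        }
        if (is.null(goal)) goal <- cc[pick_target(key), c("lon", "lat")]
        d_goal <- gc_dist_km(lon, lat, goal$lon, goal$lat)
        if (phase == "out" && d_goal <= 30) {
          phase <- "forage"; steps_in_phase <- 0L
        } else if (phase == "forage" && steps_in_phase > forage_target) {
          phase <- "return"; steps_in_phase <- 0L
        }
        bear_col <- geosphere::bearing(c(lon, lat), colony)
        if (phase == "return") {
          h <- bear_col + rnorm(1, 0, 15)
          cand <- gc_destination(lon, lat, h, runif(1, 5, 25) * gap)
          if (!is.na(cell_at(grid, cand$lon, cand$lat))) {
            lon <- cand$lon; lat <- cand$lat; heading <- h
          }
        } else {
          ## step selection: candidate steps are drawn from the biased
          ## CRW and one is kept with probability proportional to the
          ## inverse-logit suitability at its destination cell; the
          ## forage phase loses heading persistence (area-restricted
          ## search), which is where habitat selection accumulates
          if (dcol > 0.7 * max_range_km) {
            mu <- bear_col; sd_h <- 45
          } else if (phase == "forage") {
            mu <- heading; sd_h <- 120
          } else {
            mu <- geosphere::bearing(c(lon, lat), c(goal$lon, goal$lat))
            sd_h <- 25
          }
          speed <- if (phase == "forage") runif(7, 3, 12) else runif(7, 5, 25)
          hs <- mu + rnorm(7, 0, sd_h)
          cand <- gc_destination(lon, lat, hs, speed * gap)
          cells <- cell_at(grid, cand$lon, cand$lat)
          ok <- !is.na(cells) &
            gc_dist_km(cand$lon, cand$lat, colony[1], colony[2]) <=
              0.98 * max_range_km
          if (any(ok)) {
            w <- suit[[key]][cells]
            w[!ok] <- 0
            pick <- sample.int(7, 1, prob = w)
            lon <- cand$lon[pick]; lat <- cand$lat[pick]
            heading <- hs[pick]
          }
        }
        steps_in_phase <- steps_in_phase + 1L
        out[s, ] <- c(as.numeric(tm), lon, lat)
      }
      df <- data.frame(
        id = sprintf("A%02d", a),
        timestamp = as.POSIXct(out[, 1], origin = "1970-01-01", tz = "UTC"),
        lon = out[, 2], lat = out[, 3], device = "PTT",
        stringsAsFactors = FALSE)
      ## ARGOS-like outliers: displaced so both adjacent segments imply
      ## > 65 km/h (gap <= 4 * cadence_h, displacement >= 700 km), while
      ## staying within 0.9 * max_range of the colony.
      n_out <- round(outlier_rate * n_steps)
      if (n_out > 0) {
        idx <- sample(2:(n_steps - 1), n_out)
        for (i in idx) {
          repeat {
            r <- 0.9 * max_range_km * sqrt(runif(1))
            p <- gc_destination(colony[1], colony[2], runif(1, 0, 360), r)
            if (gc_dist_km(p$lon, p$lat, df$lon[i], df$lat[i]) >= 700) break
          }
          df$lon[i] <- p$lon; df$lat[i] <- p$lat
        }
      }
      res[[a]] <- df
    }
    do.call(rbind, res)
  })
}

#' Simulate a strip-transect survey
#'
#' Places 10-min observation bins along straight transect legs (10 kn,
#' 500 m strip by default, so each bin surveys about 1.54 km^2). Each
#' campaign is assigned one (month, year) period of the seascape. Per-taxon
#' presence is Bernoulli with probability
#' `plogis(truth linear predictor + campaign random intercept)`, the
#' random intercept drawn Normal(0, sigma) per campaign with each taxon's
#' own sigma; covariates are standardized over the realized bins, so truth
#' coefficients are on the z-score scale of the generated survey. Counts
#' given presence are 1 + Geometric with mean 3 (cosmetic: only
#' presence/absence feeds the models).
#'
#' @param seascape A seascape.
#' @param truth_by_taxon Named list of [truth_record()]s, one per taxon.
#' @param n_campaigns Number of campaigns (>= 2, needed for a random
#'   intercept).
#' @param bins_per_campaign Bins per campaign (>= 1).
#' @param seed Integer seed.
#' @param speed_kn Vessel speed in knots (default 10).
#' @param bin_minutes Bin duration in minutes (default 10).
#' @param strip_width_km Strip width in km (default 0.5).
#' @param bin_spacing_km Distance between bin midpoints; defaults to the
#'   bin length (contiguous 10-min bins). Larger spacing yields spatially
#'   thinned designs with about one bin per grid cell.
#' @return data.frame with columns `campaign`, `bin`, `year`, `month`,
#'   `date`, `lon`, `lat`, `effort_km2` and one `count_<taxon>` column per
#'   taxon; attribute `taxa` lists taxon names.
#' @export
simulate_survey <- function(seascape, truth_by_taxon, n_campaigns,
                            bins_per_campaign, seed = NULL, speed_kn = 10,
                            bin_minutes = 10, strip_width_km = 0.5,
                            bin_spacing_km = NULL) {
  if (n_campaigns < 2)
    stop("at least 2 campaigns are required for a random intercept")
  if (bins_per_campaign < 1) stop("empty transect set: bins_per_campaign >= 1")
  stopifnot(is.list(truth_by_taxon), length(names(truth_by_taxon)) > 0)
  bin_len_km <- speed_kn * 1.852 * bin_minutes / 60
  effort_km2 <- strip_width_km * bin_len_km
  spacing <- bin_spacing_km %||% bin_len_km
  with_seed(seed, {
    grid <- seascape$grid
    keys <- names(seascape$dynamic)
    rows <- vector("list", n_campaigns)
    for (cmp in seq_len(n_campaigns)) {
      key <- keys[(cmp - 1L) %% length(keys) + 1L]
      yr <- as.integer(substr(key, 1, 4)); mo <- as.integer(substr(key, 6, 7))
      lon <- runif(1, grid$bbox[1] + 0.2, grid$bbox[2] - 0.2)
      lat <- runif(1, grid$bbox[3] + 0.2, grid$bbox[4] - 0.2)
      heading <- runif(1, 0, 360)
      pos <- matrix(NA_real_, bins_per_campaign, 2)
      for (b in seq_len(bins_per_campaign)) {
        pos[b, ] <- c(lon, lat)
        repeat {
          dest <- gc_destination(lon, lat, heading, spacing)
          inside <- dest$lon > grid$bbox[1] && dest$lon < grid$bbox[2] &&
            dest$lat > grid$bbox[3] && dest$lat < grid$bbox[4]
          if (inside) break
          ## new leg: turn back toward the interior
          heading <- geosphere::bearing(
            c(lon, lat), c(mean(grid$bbox[1:2]), mean(grid$bbox[3:4]))) +
            rnorm(1, 0, 30)
        }
        lon <- dest$lon; lat <- dest$lat
      }
      rows[[cmp]] <- data.frame(
        campaign = sprintf("C%02d", cmp), bin = seq_len(bins_per_campaign),
        year = yr, month = mo,
        date = as.Date(sprintf("%d-%02d-15", yr, mo)),
        lon = pos[, 1], lat = pos[, 2], effort_km2 = effort_km2,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$cell <- cell_at(grid, tab$lon, tab$lat)
    ## covariates at the bin's cell, per campaign period
    cov_all <- covariate_names()
    for (v in cov_all) tab[[v]] <- NA_real_
    for (key in unique(paste(tab$year, tab$month))) {
      sel <- paste(tab$year, tab$month) == key
      yr <- tab$year[sel][1]; mo <- tab$month[sel][1]
      cov <- seascape_covariates(seascape, mo, yr)
      for (v in cov_all) tab[[v]][sel] <- cov[[v]][tab$cell[sel]]
    }
    ## z-score over the realized bins: the scale truth coefficients act on
    zc <- lapply(cov_all, function(v) {
      s <- sd(tab[[v]])
      if (is.na(s) || s == 0) rep(0, nrow(tab))
      else (tab[[v]] - mean(tab[[v]])) / s
    })
    z <- as.data.frame(setNames(zc, cov_all))
    taxa <- names(truth_by_taxon)
    for (tx in taxa) {
      truth <- truth_by_taxon[[tx]]
      b_c <- rnorm(n_campaigns, 0, truth$sigma)
      lp <- truth_lp(truth, z) + b_c[as.integer(factor(tab$campaign))]
      pres <- rbinom(nrow(tab), 1, plogis(lp))
      cnt <- ifelse(pres == 1, 1 + rgeom(nrow(tab), 1 / 3), 0)
      tab[[paste0("count_", tx)]] <- cnt
    }
    tab$cell <- NULL
    for (v in cov_all) tab[[v]] <- NULL
    attr(tab, "taxa") <- taxa
    rownames(tab) <- NULL
    tab
  })
}
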