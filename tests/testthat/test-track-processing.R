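test_that("speed filter keeps plausible fixes and drops spikes", {
  # two points 10 km / 1 h apart: both kept
  t2 <- make_traj(c(45, 45.09), c(-19, -19), gap_h = 1)
  expect_equal(nrow(speed_filter(t2, 65)), 2)

  # A-B-C: A->B and B->C ~100 km/h but A->C slow: B removed
  b <- gc_destination(45, -19, 90, 100)
  c_ <- gc_destination(45, -19, 90, 20)
  t3 <- make_traj(c(45, b$lon, c_$lon), c(-19, b$lat, c_$lat), gap_h = 1)
  f <- speed_filter(t3, 65)
  expect_equal(nrow(f), 2)
  expect_equal(f$lon, c(45, c_$lon))
  # brute-force recheck: all consecutive pair speeds now below the limit
  expect_true(all(hotspotr:::segment_speeds_kmh(f) <= 65))

  expect_error(speed_filter(make_traj(c(1, 2), c(1, 2), gap_h = -1)),
               "strictly increasing")
})

test_that("speed filter is idempotent and exhaustively valid on noisy tracks", {
  ss <- small_seascape()
  truth <- truth_record(c(INT = 0, Chloa = 0.5), sigma = 0)
  tk <- simulate_tracks(ss, truth, n_animals = 3, seed = 99, n_steps = 150,
                        outlier_rate = 0.1)
  f1 <- speed_filter(tk, 65)
  for (id in unique(f1$id)) {
    sp <- hotspotr:::segment_speeds_kmh(f1[f1$id == id, ])
    expect_true(all(sp <= 65))
  }
  expect_identical(speed_filter(f1, 65), f1)
  # first fix of each animal survives
  for (id in unique(tk$id))
    expect_equal(f1$timestamp[f1$id == id][1], tk$timestamp[tk$id == id][1])
})

test_that("trip splitting separates breeding and non-breeding movement", {
  colony <- c(45, -19)
  away1 <- gc_destination(45, -19, 90, 50)
  away2 <- gc_destination(45, -19, 270, 80)
  far <- gc_destination(45, -19, 180, 300)
  # leaves and returns twice: two breeding trips
  tr <- make_traj(c(45, away1$lon, 45, away2$lon, 45),
                  c(-19, away1$lat, -19, away2$lat, -19), gap_h = 5)
  s <- split_trips(tr, colony, 5)
  expect_equal(sort(unique(na.omit(s$trip))), c("T1_T01", "T1_T02"))
  expect_true(all(na.omit(s$status) == "breeding"))
  expect_true(all(is.na(s$trip[c(1, 3, 5)])))

  # leaves and never returns: one non-breeding trip
  tr2 <- make_traj(c(45, away1$lon, far$lon), c(-19, away1$lat, far$lat),
                   gap_h = 10)
  s2 <- split_trips(tr2, colony, 5)
  expect_equal(unique(na.omit(s2$trip)), "T1_T01")
  expect_equal(unique(na.omit(s2$status)), "non-breeding")

  # all positions at the colony: zero trips
  s3 <- split_trips(make_traj(c(45, 45.01, 45), c(-19, -19.01, -19)), colony, 5)
  expect_true(all(is.na(s3$trip)))

  # trip labels partition all off-colony positions
  ss <- small_seascape()
  tk <- simulate_tracks(ss, truth_record(c(INT = 0), sigma = 0),
                        n_animals = 2, seed = 4, n_steps = 120)
  s4 <- split_trips(tk, ss$colony, 5)
  off <- gc_dist_km(s4$lon, s4$lat, ss$colony[1], ss$colony[2]) > 5
  expect_true(all(!is.na(s4$trip[off])))
  expect_true(all(is.na(s4$trip[!off])))
})

test_that("resampling thins dense tracks to the target cadence", {
  set.seed(2)
  n <- 2000
  tr <- make_traj(45 + cumsum(rnorm(n, 0, 0.001)),
                  -19 + cumsum(rnorm(n, 0, 0.001)), gap_h = rep(0.1, n - 1))
  rs <- resample_track(tr, 1.57, seed = 6)
  gap <- mean(diff(as.numeric(rs$timestamp)) / 3600)
  expect_lt(abs(gap - 1.57) / 1.57, 0.2)
  expect_identical(rs, resample_track(tr, 1.57, seed = 6))
  # target below the native cadence: identity with a warning
  sparse <- make_traj(c(45, 45.1, 45.2), c(-19, -19, -19), gap_h = 3)
  expect_warning(out <- resample_track(sparse, 1.57), "sparser")
  expect_identical(out, sparse)
})

test_that("kernel UD conserves mass and nests its contours", {
  g <- build_grid(c(40, 44, -22, -18), 0.25)
  # single point: unit mass, maximum at the nearest cell
  ud1 <- kernel_ud(data.frame(lon = 41.62, lat = -19.38), g, h = 0.5)
  expect_equal(sum(ud1$density) * 0.25^2, 1, tolerance = 1e-6)
  peak <- which(ud1$density == max(ud1$density))
  cc <- cell_centers(g)
  d_peak <- gc_dist_km(cc$lon, cc$lat, 41.62, -19.38)
  ri <- (peak - 1) %% g$nlat + 1; ci <- (peak - 1) %/% g$nlat + 1
  peak_cell <- (ri - 1) * g$nlon + ci
  expect_equal(peak_cell, which.min(d_peak))

  set.seed(3)
  pts <- data.frame(lon = rnorm(200, 42, 0.6), lat = rnorm(200, -20, 0.6))
  ud <- kernel_ud(pts, g, h = 0.5)
  expect_equal(sum(ud$density) * 0.25^2, 1, tolerance = 1e-6)
  masks <- ud_contours(ud)
  expect_true(all(masks[["25"]] <= masks[["50"]]))
  expect_true(all(masks[["50"]] <= masks[["75"]]))
  expect_true(all(masks[["75"]] <= masks[["95"]]))
  # each mask reaches its target mass and is minimal
  area <- 0.25^2
  for (L in c(25, 50, 75, 95)) {
    m <- masks[[as.character(L)]]
    expect_gte(sum(ud$density[m]) * area, L / 100)
    expect_lt((sum(ud$density[m]) - min(ud$density[m])) * area, L / 100)
  }
  expect_error(kernel_ud(data.frame(lon = numeric(), lat = numeric()), g),
               "empty")
})

test_that("ring of points yields nested masks containing the ring", {
  g <- build_grid(c(40, 44, -22, -18), 0.25)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- data.frame(lon = 42 + cos(th), lat = -20 + sin(th))
  ud <- kernel_ud(pts, g, h = 0.3)
  masks <- ud_contours(ud, c(50, 95))
  a50 <- sum(masks[["50"]]); a95 <- sum(masks[["95"]])
  expect_lt(a50, a95)
  # direct mass-accumulation oracle: the 95% mask holds >= 95% of mass
  expect_gte(sum(ud$density[masks[["95"]]]) * 0.25^2, 0.95)
  ring_cells <- unique(cell_at(g, pts$lon, pts$lat))
  ri <- (ring_cells - 1) %/% g$nlon + 1; ci <- (ring_cells - 1) %% g$nlon + 1
  expect_true(all(masks[["95"]][cbind(ri, ci)]))
})
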