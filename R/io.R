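#' Read and write trajectory / survey / occurrence tables as CSV
#'
#' Plain CSV round-trip helpers. Trajectory timestamps are written as
#' ISO-8601 UTC strings and parsed back to POSIXct.
#'
#' @param traj,survey,table data.frame to write.
#' @param path File path.
#' @return Readers return the parsed data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- traj
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                            tz = "UTC")
  check_trajectory(d)
  d
}

#' @rdname write_trajectory_csv
#' @export
write_survey_csv <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_survey_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  attr(d, "taxa") <- sub("^count_", "", grep("^count_", names(d), value = TRUE))
  d
}

#' Write a gridded layer as long-format CSV
#'
#' One row per cell (`cell`, `lon`, `lat`, `value`), aligned to the
#' standard grid; the portable plain-text exchange format used for all
#' map layers.
#'
#' @param layer Numeric matrix `[nlat, nlon]`.
#' @param grid A `std_grid`.
#' @param path File path.
#' @export
write_layer_csv <- function(layer, grid, path) {
  cc <- cell_centers(grid)
  cc$value <- layer_values(layer, cc$cell)
  write.csv(cc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layer_csv
#' @export
read_layer_csv <- function(path, grid) {
  d <- read.csv(path)
  layer_from_cells(grid, d$cell, d$value)
}
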