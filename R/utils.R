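#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.formula complete.cases cor dnorm logLik
#'   median optim pnorm plogis qlogis quantile rbinom rexp rgamma rgeom
#'   rnorm runif sd setNames vcov AIC
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs recycle like
#' [geosphere::distHaversine()].
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

## Destination point given start, bearing (deg, clockwise from north) and
## distance in km. Thin wrapper so all movement code shares one Earth radius.
gc_destination <- function(lon, lat, bearing, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, dist_km, r = 6371)
  data.frame(lon = p[, 1], lat = p[, 2])
}

## set.seed only when the caller supplied one; sub-seeds derived by small
## offsets must stay below 2^31.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), seed == floor(seed))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

## Named per-stage sub-seed derived from a master seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}
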