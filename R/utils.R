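NMI_M <- 1852            # metres per nautical mile
EARTH_RADIUS_M <- 6371000  # spherical Earth radius used for all distances

.log <- function(...) {
  if (isTRUE(getOption("echoscape.verbose", TRUE)))
    message("[echoscape] ", sprintf(...))
}

#' Great-circle distance in nautical miles
#'
#' Haversine distance on a sphere of radius 6371 km, the scale-appropriate
#' choice for sub-metre accuracy over the 0.1 nmi cells used here.
#'
#' @param lat1,lon1,lat2,lon2 positions in decimal degrees (vectorised).
#' @return distance in nautical miles.
#' @export
#' @examples
#' haversineNmi(0, 0, 0, 1 / 60)  # one minute of longitude at the equator
haversineNmi <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / NMI_M
}

# Cumulative along-track distance (nmi) over a ping sequence.
.trackDistance <- function(lat, lon) {
  n <- length(lat)
  if (n < 2) return(rep(0, n))
  seg <- haversineNmi(lat[-n], lon[-n], lat[-1], lon[-1])
  c(0, cumsum(seg))
}

# Deterministic sub-seed for a pipeline stage, so stages are independently
# reproducible from one master seed. Kept below 2^31 - 1.
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

# Linear interpolation of a CTD profile variable onto target depths;
# constant extrapolation at the ends (rule = 2).
.interpProfile <- function(depth, values, target) {
  stats::approx(depth, values, xout = target, rule = 2)$y
}

.asUTC <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}
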