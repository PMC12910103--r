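#' dB / linear intensity conversion
#'
#' Volume backscattering strength averages are taken in the linear intensity
#' domain: `dbToLinear(x)` is `10^(x/10)` and `linearToDb()` its exact
#' inverse. All "mean Sv" values in this package are `linearToDb(mean(
#' dbToLinear(sv)))` over non-missing samples.
#'
#' @param sv numeric, dB.
#' @param x numeric, linear intensity (> 0).
#' @return the converted values.
#' @export
#' @examples
#' dbToLinear(-70)                      # 1e-7
#' linearToDb(mean(dbToLinear(c(-70, -60))))  # -62.59 dB
dbToLinear <- function(sv) 10^(sv / 10)

#' @rdname dbToLinear
#' @export
linearToDb <- function(x) 10 * log10(x)

# Linear-domain mean of dB values, NA-excluded; NA when nothing remains.
.meanDb <- function(sv) {
  sv <- sv[!is.na(sv)]
  if (!length(sv)) return(NA_real_)
  linearToDb(mean(dbToLinear(sv)))
}

#' Exclude the near-surface stratum of an echogram
#'
#' Drops all samples shallower than `offset_m` (bin centres compared to the
#' offset), the standard guard against integrating surface air bubbles and
#' the transducer near field. The default pipeline uses 10 m.
#'
#' @param e an [Echogram].
#' @param offset_m exclusion depth (m); must be shallower than the deepest
#'   sample.
#' @return the trimmed [Echogram].
#' @export
applySurfaceOffset <- function(e, offset_m) {
  d <- depthAxis(e)
  if (offset_m >= max(d))
    stop(sprintf("surface offset (%g m) is not shallower than the grid (%g m)",
                 offset_m, max(d)))
  keep <- d >= offset_m
  if (all(keep)) return(e)
  .log("surface offset %g m: dropped %d of %d depth bins", offset_m,
       sum(!keep), length(keep))
  Echogram(svMatrix(e)[keep, , drop = FALSE], d[keep], pingTimes(e),
           pingPositions(e)$lat, pingPositions(e)$lon, frequencyKHz(e))
}

#' Echo-integrate an echogram into distance-by-depth cells
#'
#' Pings are partitioned into contiguous along-track blocks of
#' `distance_nmi` extent (cumulative great-circle distance between
#' successive pings; haversine on a 6371 km sphere) and samples into
#' half-open `depth_bin_m` bins anchored at 0 m. Each cell's Sv is the dB of
#' the arithmetic mean of linear backscatter over its non-missing member
#' samples, so total linear energy is conserved exactly. Cell time and
#' position are the means over member pings; columns are ordered by track
#' distance. A zero-length track (stationary ship) yields a single-column
#' grid with a warning.
#'
#' @param e an [Echogram].
#' @param distance_nmi along-track cell size (nautical miles).
#' @param depth_bin_m vertical cell size (m).
#' @return an [IntegrationGrid].
#' @export
echoIntegrate <- function(e, distance_nmi = 0.1, depth_bin_m = 1) {
  pos <- pingPositions(e)
  cum <- .trackDistance(pos$lat, pos$lon)
  if (max(cum) == 0 && ncol(e) > 1) {
    warning("all ping positions identical: zero track length, single-column grid")
    block <- rep(1L, ncol(e))
  } else {
    block <- as.integer(floor(cum / distance_nmi)) + 1L
  }
  d <- depthAxis(e)
  dbin <- as.integer(floor(d / depth_bin_m)) + 1L
  sv_lin <- dbToLinear(svMatrix(e))
  miss <- is.na(sv_lin)
  sv_lin[miss] <- 0

  ublock <- sort(unique(block))
  ubin <- sort(unique(dbin))
  bi <- match(dbin, ubin)
  bj <- match(block, ublock)
  # row-group then column-group sums of linear energy and sample counts
  rsum <- rowsum(sv_lin, bi)
  rcnt <- rowsum((!miss) * 1, bi)
  csum <- t(rowsum(t(rsum), bj))
  ccnt <- t(rowsum(t(rcnt), bj))
  sv <- ifelse(ccnt > 0, linearToDb(csum / pmax(ccnt, 1)), NA_real_)

  times <- pingTimes(e)
  cell_time <- .asUTC(vapply(split(as.numeric(times), bj), mean, numeric(1)))
  cell_lat <- vapply(split(pos$lat, bj), mean, numeric(1))
  cell_lon <- vapply(split(pos$lon, bj), mean, numeric(1))
  cell_dist <- vapply(split(cum, bj), mean, numeric(1))

  .IntegrationGrid(sv, ccnt,
                   depth_top = (ubin - 1) * depth_bin_m,
                   depth_bottom = ubin * depth_bin_m,
                   time = cell_time, lat = cell_lat, lon = cell_lon,
                   distance_nmi = cell_dist, frequency_khz = frequencyKHz(e),
                   cell_distance_nmi = distance_nmi, depth_bin_m = depth_bin_m)
}

#' Threshold mask over an integration grid
#'
#' `TRUE` where a cell's Sv is at or above the extraction threshold and
#' non-missing. The comparison is inclusive, so a cell at exactly the
#' threshold is kept.
#'
#' @param g an [IntegrationGrid].
#' @param threshold_db extraction threshold (dB), -70 by default.
#' @return logical matrix with the grid's dimensions.
#' @export
thresholdMask <- function(g, threshold_db = -70) {
  sv <- svMatrix(g)
  !is.na(sv) & sv >= threshold_db
}
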