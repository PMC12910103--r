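#' Construct an Echogram
#'
#' @param sv numeric matrix of volume backscattering strength (dB re 1/m),
#'   rows = depth bins, columns = pings; missing samples `NA`.
#' @param depth_m numeric depth-bin centres (m below surface), strictly
#'   increasing with uniform step.
#' @param ping_time POSIXct (UTC) per ping, non-decreasing.
#' @param lat,lon numeric per-ping position, decimal degrees.
#' @param frequency_khz acoustic frequency in kHz.
#' @return a validated [Echogram].
#' @export
#' @examples
#' eg <- Echogram(matrix(-80, 3, 2), depth_m = c(10.5, 11.5, 12.5),
#'                ping_time = as.POSIXct(c("2021-12-11 12:00:00",
#'                                         "2021-12-11 12:00:10"), tz = "UTC"),
#'                lat = c(28, 28), lon = c(-15.5, -15.5), frequency_khz = 38)
#' depthAxis(eg)
Echogram <- function(sv, depth_m, ping_time, lat, lon, frequency_khz) {
  stopifnot(is.matrix(sv), nrow(sv) == length(depth_m),
            ncol(sv) == length(ping_time),
            length(lat) == length(ping_time), length(lon) == length(ping_time))
  ping_time <- .asUTC(ping_time)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(sv = unname(sv)),
    rowData = DataFrame(depth_m = as.numeric(depth_m)),
    colData = DataFrame(ping_time = ping_time, lat = as.numeric(lat),
                        lon = as.numeric(lon)),
    metadata = list(frequency_khz = as.numeric(frequency_khz)))
  new("Echogram", se)
}

# Internal grid constructor; echoIntegrate() is the user entry point.
.IntegrationGrid <- function(sv, n, depth_top, depth_bottom, time, lat, lon,
                             distance_nmi, frequency_khz, cell_distance_nmi,
                             depth_bin_m) {
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(sv = unname(sv), n = unname(n)),
    rowData = DataFrame(depth_m = (depth_top + depth_bottom) / 2,
                        depth_top_m = depth_top, depth_bottom_m = depth_bottom),
    colData = DataFrame(time = .asUTC(time), lat = lat, lon = lon,
                        distance_nmi = distance_nmi),
    metadata = list(frequency_khz = frequency_khz,
                    cell_distance_nmi = cell_distance_nmi,
                    depth_bin_m = depth_bin_m))
  new("IntegrationGrid", se)
}

#' Construct a CTDStation
#'
#' @param station_id character label.
#' @param lat,lon position in decimal degrees.
#' @param time POSIXct cast time (UTC).
#' @param profile data.frame with columns `depth_m`, `temperature`,
#'   `salinity`, `oxygen`, `chlorophyll_a`, `par` and optionally `turbidity`.
#' @return a validated [CTDStation].
#' @export
CTDStation <- function(station_id, lat, lon, time, profile) {
  new("CTDStation", station_id = as.character(station_id), lat = as.numeric(lat),
      lon = as.numeric(lon), time = .asUTC(time),
      profile = as.data.frame(profile))
}

#' @describeIn CTDStation profile data.frame of a station.
#' @param x a `CTDStation`.
#' @export
ctdProfile <- function(x) x@profile

#' @describeIn CTDStation station position as `c(lat, lon)`.
#' @export
stationPosition <- function(x) c(lat = x@lat, lon = x@lon)

#' @rdname accessors
setMethod("svMatrix", "SummarizedExperiment", function(x) assays(x)[["sv"]])
#' @rdname accessors
setMethod("depthAxis", "SummarizedExperiment", function(x) rowData(x)$depth_m)
#' @rdname accessors
setMethod("pingTimes", "Echogram", function(x) colData(x)$ping_time)
#' @rdname accessors
setMethod("pingTimes", "IntegrationGrid", function(x) colData(x)$time)
#' @rdname accessors
setMethod("pingPositions", "SummarizedExperiment", function(x)
  data.frame(lat = colData(x)$lat, lon = colData(x)$lon))
#' @rdname accessors
setMethod("frequencyKHz", "SummarizedExperiment", function(x)
  metadata(x)$frequency_khz)
#' @rdname accessors
setMethod("nSamples", "IntegrationGrid", function(x) assays(x)[["n"]])
#' @rdname accessors
setMethod("cellDistances", "IntegrationGrid", function(x) colData(x)$distance_nmi)

setMethod("show", "Echogram", function(object) {
  cat(sprintf("Echogram: %d depth bins x %d pings at %g kHz\n",
              nrow(object), ncol(object), frequencyKHz(object)))
  d <- depthAxis(object)
  if (length(d))
    cat(sprintf("  depth %.1f-%.1f m; Sv range %s dB; %.1f%% missing\n",
                min(d), max(d),
                paste(round(range(svMatrix(object), na.rm = TRUE), 1),
                      collapse = " to "),
                100 * mean(is.na(svMatrix(object)))))
})

setMethod("show", "IntegrationGrid", function(object) {
  cat(sprintf(
    "IntegrationGrid: %d depth bins x %d cells (%g nmi x %g m) at %g kHz\n",
    nrow(object), ncol(object), metadata(object)$cell_distance_nmi,
    metadata(object)$depth_bin_m, frequencyKHz(object)))
})

setMethod("show", "CTDStation", function(object) {
  cat(sprintf("CTDStation %s at (%.3f, %.3f), %s; %d depths to %.0f m\n",
              object@station_id, object@lat, object@lon,
              format(object@time, "%Y-%m-%d %H:%M UTC"),
              nrow(object@profile), max(object@profile$depth_m)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, paste(slot(object, s), collapse = "..")))
})

setMethod("show", "LayerSpec", function(object) {
  cat(sprintf(
    "LayerSpec: day %g m / night %g m, sigma %g m, peak %g dB%s (%s)\n",
    object@day_center_depth, object@night_center_depth, object@sigma_depth,
    object@peak_sv, if (object@persistent) ", persistent" else "",
    object@diel_presence))
})

setMethod("show", "RegionPreset", function(object) {
  cat(sprintf("RegionPreset '%s' at (%.1f, %.1f): %d layers, floor %g dB\n",
              object@name, object@lat, object@lon, length(object@layers),
              object@noise_floor_sv))
})

setMethod("show", "SeascapeClassification", function(object) {
  cat(sprintf("SeascapeClassification (%s): %d units, k = %d\n",
              object@unit, nrow(object@descriptors), object@k))
  cat("  mean silhouette by k:",
      paste(sprintf("%s:%.3f", names(object@silhouette_by_k),
                    object@silhouette_by_k), collapse = " "), "\n")
})

setMethod("show", "GAMResult", function(object) {
  cat(sprintf("GAMResult for %s: deviance explained %.1f%%, AIC %.1f\n",
              object@response, object@deviance_explained, object@aic))
  print(object@terms, row.names = FALSE)
})

#' @rdname cluster-accessors
setMethod("selectedK", "SeascapeClassification", function(x) x@k)
#' @rdname cluster-accessors
setMethod("clusterLabels", "SeascapeClassification", function(x) x@labels)
#' @rdname cluster-accessors
setMethod("silhouetteByK", "SeascapeClassification", function(x) x@silhouette_by_k)
#' @rdname cluster-accessors
setMethod("clusterSummaries", "SeascapeClassification", function(x) x@summaries)

#' @rdname gam-accessors
setMethod("devianceExplained", "GAMResult", function(x) x@deviance_explained)
#' @rdname gam-accessors
setMethod("termTable", "GAMResult", function(x) x@terms)
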