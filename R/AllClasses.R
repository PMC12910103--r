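#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Echogram: a depth-by-ping grid of volume backscattering strength
#'
#' An `Echogram` holds calibrated volume backscattering strength
#' (Sv, dB re 1 m\eqn{^{-1}}) on a regular depth axis, one column per ping,
#' together with per-ping navigation (UTC time, latitude, longitude) and the
#' acoustic frequency. It extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the `"sv"` assay is the Sv matrix, `rowData` carries the depth axis and
#' `colData` the ping metadata, so all the usual subsetting and accessor
#' machinery applies. Missing samples (dropout pings, excluded near-surface
#' bins) are `NA`; they are excluded from every average downstream, never
#' treated as zero backscatter.
#'
#' Depth convention: metres below the sea surface, positive downward; the
#' depth axis gives bin centres of half-open bins `[z, z + dz)`.
#'
#' @slot .Data see `SummarizedExperiment`.
#' @seealso [Echogram()] for construction, [readEchogram()] to read one from
#'   disk, [generateEchogram()] to simulate one.
#' @export
setClass("Echogram", contains = "SummarizedExperiment")

.validEchogram <- function(object) {
  msg <- character()
  if (!"sv" %in% names(assays(object)))
    msg <- c(msg, "assay 'sv' is required")
  d <- rowData(object)$depth_m
  if (is.null(d)) {
    msg <- c(msg, "rowData must contain 'depth_m'")
  } else {
    if (length(d) && d[1] < 0) msg <- c(msg, "depth axis must start at >= 0 m")
    dd <- diff(d)
    if (length(dd) && (any(dd <= 0) || diff(range(dd)) > 1e-6 * mean(dd)))
      msg <- c(msg, "depth axis must be strictly increasing with uniform step")
  }
  cd <- colData(object)
  for (nm in c("ping_time", "lat", "lon"))
    if (!nm %in% names(cd)) msg <- c(msg, sprintf("colData must contain '%s'", nm))
  if ("ping_time" %in% names(cd) && is.unsorted(cd$ping_time))
    msg <- c(msg, "ping times must be non-decreasing")
  if ("lat" %in% names(cd) && length(cd$lat) && any(abs(cd$lat) > 90, na.rm = TRUE))
    msg <- c(msg, "latitudes must lie in [-90, 90]")
  if ("lon" %in% names(cd) && length(cd$lon) && any(abs(cd$lon) > 180, na.rm = TRUE))
    msg <- c(msg, "longitudes must lie in [-180, 180]")
  if (is.null(metadata(object)$frequency_khz))
    msg <- c(msg, "metadata must record 'frequency_khz'")
  sv <- assays(object)[["sv"]]
  if (!is.null(sv) && any(is.infinite(sv)))
    msg <- c(msg, "non-missing sv values must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("Echogram", .validEchogram)

#' IntegrationGrid: echo-integrated Sv cells
#'
#' Result of echo-integrating an [Echogram] into fixed along-track distance
#' by depth cells (0.1 nmi by 1 m in the default configuration). The `"sv"`
#' assay holds, per cell, the dB value of the *arithmetic mean of linear*
#' backscatter over the member samples; the `"n"` assay counts those samples.
#' `colData` carries the mean time and position of each along-track cell and
#' its cumulative track distance; `rowData` the depth-bin centres and edges.
#'
#' @seealso [echoIntegrate()]
#' @export
setClass("IntegrationGrid", contains = "SummarizedExperiment")

.validIntegrationGrid <- function(object) {
  msg <- character()
  for (a in c("sv", "n"))
    if (!a %in% names(assays(object)))
      msg <- c(msg, sprintf("assay '%s' is required", a))
  rd <- rowData(object)
  for (nm in c("depth_m", "depth_top_m", "depth_bottom_m"))
    if (!nm %in% names(rd)) msg <- c(msg, sprintf("rowData must contain '%s'", nm))
  cd <- colData(object)
  for (nm in c("time", "lat", "lon", "distance_nmi"))
    if (!nm %in% names(cd)) msg <- c(msg, sprintf("colData must contain '%s'", nm))
  if (all(c("sv", "n") %in% names(assays(object)))) {
    n <- assays(object)[["n"]]
    sv <- assays(object)[["sv"]]
    if (any(!is.na(sv) & n < 1))
      msg <- c(msg, "non-missing cells must have n_samples >= 1")
  }
  if (length(msg)) msg else TRUE
}
setValidity("IntegrationGrid", .validIntegrationGrid)

#' CTDStation: a hydrographic station profile
#'
#' One CTD cast: position and time of the station plus vertical profiles of
#' temperature (degC), salinity (PSU), dissolved oxygen (umol/kg),
#' chlorophyll-a (ug/m^3) and photosynthetically active radiation
#' (umol m^-2 s^-1), with optional turbidity. Profiles share one depth axis.
#'
#' @slot station_id character station label.
#' @slot lat,lon numeric position, decimal degrees.
#' @slot time POSIXct cast time (UTC).
#' @slot profile data.frame with column `depth_m` plus the variables above.
#' @export
setClass("CTDStation",
  representation(station_id = "character", lat = "numeric", lon = "numeric",
                 time = "POSIXct", profile = "data.frame"))

.ctdVars <- c("temperature", "salinity", "oxygen", "chlorophyll_a", "par")

.validCTDStation <- function(object) {
  msg <- character()
  p <- object@profile
  if (!"depth_m" %in% names(p)) msg <- c(msg, "profile must contain 'depth_m'")
  for (v in .ctdVars)
    if (!v %in% names(p)) msg <- c(msg, sprintf("profile must contain '%s'", v))
  if (!length(msg)) {
    if (any(p$oxygen < 0, na.rm = TRUE)) msg <- c(msg, "oxygen must be >= 0")
    if (any(p$salinity <= 0 | p$salinity >= 45, na.rm = TRUE))
      msg <- c(msg, "salinity must lie in (0, 45) PSU")
    if (any(p$par < 0, na.rm = TRUE)) msg <- c(msg, "PAR must be >= 0")
  }
  if (abs(object@lat) > 90) msg <- c(msg, "latitude out of range")
  if (abs(object@lon) > 180) msg <- c(msg, "longitude out of range")
  if (length(msg)) msg else TRUE
}
setValidity("CTDStation", .validCTDStation)

#' PipelineConfig: resolved analysis parameters
#'
#' All tunable parameters of the pipeline with their defaults: the -70 dB
#' extraction threshold, the 10 m surface exclusion, the 0.1 nmi by 1 m
#' echo-integration cell, the +-18 degree solar-altitude bound separating day
#' and night from crepuscular transition, the candidate range for the number
#' of seascape clusters, and segmentation/matching controls.
#'
#' @slot threshold_db numeric, Sv extraction threshold (dB), must be negative.
#' @slot surface_offset_m numeric, near-surface exclusion depth (m), >= 0.
#' @slot integration_distance_nmi numeric, along-track cell size (nmi).
#' @slot depth_bin_m numeric, vertical cell size (m).
#' @slot diel_altitude_deg numeric, solar altitude bound (degrees).
#' @slot k_range integer length-2, inclusive candidate k interval, min >= 2.
#' @slot rng_seed integer.
#' @slot cluster_unit character, `"per_day"` or `"per_layer"`.
#' @slot min_cells integer, minimum component size kept as a layer.
#' @slot n_init integer, k-means restarts.
#' @slot jaccard_min numeric, cross-frequency layer matching threshold.
#' @seealso [pipelineConfig()], [loadConfig()]
#' @export
setClass("PipelineConfig",
  representation(threshold_db = "numeric", surface_offset_m = "numeric",
                 integration_distance_nmi = "numeric", depth_bin_m = "numeric",
                 diel_altitude_deg = "numeric", k_range = "integer",
                 rng_seed = "integer", cluster_unit = "character",
                 min_cells = "integer", n_init = "integer",
                 jaccard_min = "numeric"))

.validPipelineConfig <- function(object) {
  msg <- character()
  if (object@threshold_db >= 0) msg <- c(msg, "threshold_db must be < 0 dB")
  if (object@surface_offset_m < 0) msg <- c(msg, "surface_offset_m must be >= 0")
  if (object@integration_distance_nmi <= 0)
    msg <- c(msg, "integration_distance_nmi must be > 0")
  if (object@depth_bin_m <= 0) msg <- c(msg, "depth_bin_m must be > 0")
  if (length(object@k_range) != 2 || object@k_range[1] < 2 ||
      object@k_range[2] < object@k_range[1])
    msg <- c(msg, "k_range must be c(min, max) with min >= 2")
  if (!object@cluster_unit %in% c("per_day", "per_layer"))
    msg <- c(msg, "cluster_unit must be 'per_day' or 'per_layer'")
  if (object@min_cells < 1) msg <- c(msg, "min_cells must be >= 1")
  if (object@n_init < 1) msg <- c(msg, "n_init must be >= 1")
  if (object@jaccard_min <= 0 || object@jaccard_min > 1)
    msg <- c(msg, "jaccard_min must lie in (0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("PipelineConfig", .validPipelineConfig)

#' LayerSpec: one simulated scattering layer
#'
#' Parameters of a Gaussian-in-depth scattering layer for the scene
#' generator: its daytime and night-time centre depths (the diel vertical
#' migration endpoints), Gaussian half-width, peak Sv and dB jitter on the
#' peak. `persistent = TRUE` pins the layer at its day centre (no migration);
#' `diel_presence` restricts the layer to part of the diel cycle.
#'
#' @slot day_center_depth,night_center_depth numeric, m below surface.
#' @slot sigma_depth numeric, Gaussian sigma (m).
#' @slot peak_sv numeric, dB at the layer core.
#' @slot sv_jitter_sd numeric, dB standard deviation of per-ping peak jitter.
#' @slot persistent logical.
#' @slot diel_presence character, `"always"`, `"day_only"` or `"night_only"`.
#' @export
setClass("LayerSpec",
  representation(day_center_depth = "numeric", night_center_depth = "numeric",
                 sigma_depth = "numeric", peak_sv = "numeric",
                 sv_jitter_sd = "numeric", persistent = "logical",
                 diel_presence = "character"))

.validLayerSpec <- function(object) {
  msg <- character()
  if (object@day_center_depth <= 0 || object@night_center_depth <= 0)
    msg <- c(msg, "centre depths must be > 0 m")
  if (object@sigma_depth <= 0) msg <- c(msg, "sigma_depth must be > 0 m")
  if (object@sv_jitter_sd < 0) msg <- c(msg, "sv_jitter_sd must be >= 0 dB")
  if (!object@diel_presence %in% c("always", "day_only", "night_only"))
    msg <- c(msg, "diel_presence must be 'always', 'day_only' or 'night_only'")
  if (length(msg)) msg else TRUE
}
setValidity("LayerSpec", .validLayerSpec)

#' RegionPreset: a regional scene regime
#'
#' A named oceanographic regime for the generators: the scattering-layer
#' configuration, the acoustic noise floor, the hydrographic profile
#' parameters (thermocline/halocline depths, oxygen-minimum-zone core and
#' minimum, chlorophyll maximum, PAR attenuation) and a geographic anchor.
#' Built-in presets emulate three contrasting tropical regions: the Eastern
#' Tropical North Atlantic (`"AT"`), the Sargasso Sea (`"SA"`) and the
#' Eastern Tropical Pacific (`"PA"`).
#'
#' @slot name character region code.
#' @slot layers list of [LayerSpec] objects.
#' @slot noise_floor_sv numeric, dB.
#' @slot ctd_params named list of hydrographic parameters (see
#'   [regionPreset()]).
#' @slot lat,lon numeric anchor position, decimal degrees.
#' @export
setClass("RegionPreset",
  representation(name = "character", layers = "list", noise_floor_sv = "numeric",
                 ctd_params = "list", lat = "numeric", lon = "numeric"))

.validRegionPreset <- function(object) {
  msg <- character()
  if (!all(vapply(object@layers, is, TRUE, class2 = "LayerSpec")))
    msg <- c(msg, "layers must be a list of LayerSpec objects")
  for (l in object@layers)
    if (l@peak_sv <= object@noise_floor_sv)
      msg <- c(msg, "layer peak_sv must exceed the noise floor")
  need <- c("thermocline_depth_m", "halocline_depth_m", "surface_salinity_psu",
            "omz_core_depth_m", "omz_min_oxygen", "surface_chl", "chl_max_depth_m",
            "par_attenuation_m")
  miss <- setdiff(need, names(object@ctd_params))
  if (length(miss))
    msg <- c(msg, paste("ctd_params missing:", paste(miss, collapse = ", ")))
  if (!length(msg) && object@ctd_params$omz_min_oxygen < 0)
    msg <- c(msg, "omz_min_oxygen must be >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("RegionPreset", .validRegionPreset)

#' SeascapeClassification: k-means seascape clustering result
#'
#' The standardized descriptor matrix that was clustered, the silhouette
#' curve over candidate k, the selected k, hard cluster labels, centroids in
#' standardized space, and per-cluster five-number summaries of the raw
#' descriptors.
#'
#' @slot descriptors matrix, standardized (column mean 0, sd 1).
#' @slot raw data.frame, the unstandardized descriptors plus unit metadata.
#' @slot unit character, `"per_day"` or `"per_layer"`.
#' @slot k integer, selected number of clusters.
#' @slot labels integer vector in `1..k`.
#' @slot centroids matrix, k rows, standardized space.
#' @slot silhouette_by_k named numeric, mean silhouette width per candidate k.
#' @slot summaries data.frame of per-cluster descriptor summaries.
#' @export
setClass("SeascapeClassification",
  representation(descriptors = "matrix", raw = "data.frame", unit = "character",
                 k = "integer", labels = "integer", centroids = "matrix",
                 silhouette_by_k = "numeric", summaries = "data.frame"))

.validSeascapeClassification <- function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@descriptors))
    msg <- c(msg, "one label per descriptor row is required")
  if (length(object@labels) && (min(object@labels) < 1 || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(object@silhouette_by_k) &&
      any(object@silhouette_by_k < -1 - 1e-12 | object@silhouette_by_k > 1 + 1e-12))
    msg <- c(msg, "silhouette widths must lie in [-1, 1]")
  cm <- colMeans(object@descriptors)
  if (ncol(object@descriptors) && any(abs(cm) > 1e-6))
    msg <- c(msg, "descriptor columns must be centred")
  if (length(msg)) msg else TRUE
}
setValidity("SeascapeClassification", .validSeascapeClassification)

#' GAMResult: fitted environmental driver model
#'
#' A generalized additive model of scattering-layer mean Sv against
#' standardized environmental predictors (identity link, Gaussian errors):
#' per-term estimates/EDFs and p-values, percent deviance explained, AIC,
#' fitted values and residuals, plus the underlying `mgcv::gam` fit.
#'
#' @slot response character, `"sv18"` or `"sv38"`.
#' @slot terms data.frame with columns term, type, estimate, edf, p_value.
#' @slot deviance_explained numeric, percent in \\[0, 100\\].
#' @slot aic numeric.
#' @slot fitted,residuals numeric vectors; their sum is the response.
#' @slot standardization list of predictor means/sds applied before fitting.
#' @slot model the `mgcv::gam` object.
#' @export
setClass("GAMResult",
  representation(response = "character", terms = "data.frame",
                 deviance_explained = "numeric", aic = "numeric",
                 fitted = "numeric", residuals = "numeric",
                 standardization = "list", model = "ANY"))

.validGAMResult <- function(object) {
  msg <- character()
  if (object@deviance_explained < 0 || object@deviance_explained > 100)
    msg <- c(msg, "deviance_explained must lie in [0, 100] percent")
  if (length(object@fitted) != length(object@residuals))
    msg <- c(msg, "fitted and residuals must have equal length")
  if (length(msg)) msg else TRUE
}
setValidity("GAMResult", .validGAMResult)
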