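#' Define a simulated scattering layer
#'
#' @param day_center_depth,night_center_depth daytime/night-time centre
#'   depths (m); equal values or `persistent = TRUE` give a non-migrating
#'   layer.
#' @param sigma_depth Gaussian half-width (m).
#' @param peak_sv Sv at the layer core (dB); must exceed the scene noise
#'   floor.
#' @param sv_jitter_sd per-ping dB jitter on the peak.
#' @param persistent if `TRUE` the layer stays at `day_center_depth`.
#' @param diel_presence `"always"`, `"day_only"` or `"night_only"`.
#' @return a [LayerSpec].
#' @export
layerSpec <- function(day_center_depth, night_center_depth = day_center_depth,
                      sigma_depth = 30, peak_sv = -65, sv_jitter_sd = 0.8,
                      persistent = FALSE,
                      diel_presence = c("always", "day_only", "night_only")) {
  new("LayerSpec", day_center_depth = day_center_depth,
      night_center_depth = night_center_depth, sigma_depth = sigma_depth,
      peak_sv = peak_sv, sv_jitter_sd = sv_jitter_sd, persistent = persistent,
      diel_presence = match.arg(diel_presence))
}

# Hydrographic regimes of the three regions. Values follow the contrasts
# reported for the surveyed transect: a deep (300 m) Sargasso thermocline vs
# ~100 m in the tropical Atlantic and ~50 m in the eastern Pacific; a shallow
# hypoxic Pacific OMZ reaching 20 umol/kg below 200 m vs a mild ~90 umol/kg
# minimum near 180 m in the Atlantic and a well-oxygenated Sargasso column;
# fresh (32 PSU) Pacific surface water vs salty (36-37 PSU) Atlantic gyres;
# oligotrophic Sargasso vs productive Pacific chlorophyll.
.CTD_REGIMES <- list(
  AT = list(thermocline_depth_m = 100, halocline_depth_m = 120,
            surface_salinity_psu = 36, omz_core_depth_m = 180,
            omz_min_oxygen = 90, surface_chl = 0.5, chl_max_depth_m = 50,
            par_attenuation_m = 0.06, surface_temp_c = 23, deep_temp_c = 5,
            deep_salinity_psu = 34.8, surface_oxygen = 210, omz_width_m = 120,
            chl_width_m = 30, par_surface = 1500),
  SA = list(thermocline_depth_m = 300, halocline_depth_m = 300,
            surface_salinity_psu = 37, omz_core_depth_m = 700,
            omz_min_oxygen = 195, surface_chl = 0.05, chl_max_depth_m = 120,
            par_attenuation_m = 0.04, surface_temp_c = 24, deep_temp_c = 6,
            deep_salinity_psu = 35.0, surface_oxygen = 215, omz_width_m = 250,
            chl_width_m = 40, par_surface = 1500),
  PA = list(thermocline_depth_m = 50, halocline_depth_m = 50,
            surface_salinity_psu = 32, omz_core_depth_m = 350,
            omz_min_oxygen = 20, surface_chl = 1.0, chl_max_depth_m = 35,
            par_attenuation_m = 0.08, surface_temp_c = 26, deep_temp_c = 6,
            deep_salinity_psu = 34.8, surface_oxygen = 205, omz_width_m = 150,
            chl_width_m = 25, par_surface = 1500))

# Scattering-layer regimes. Every region has a mesopelagic layer whose
# daytime core sits in the 300-700 m stratum and which ascends into the
# epipelagic (10-150 m) at night; the Pacific adds a persistent epipelagic
# layer and a daytime-only intermediate layer in the 200-500 m stratum.
.LAYER_REGIMES <- list(
  AT = list(layerSpec(430, 80, sigma_depth = 35, peak_sv = -65)),
  SA = list(layerSpec(380, 90, sigma_depth = 28, peak_sv = -67)),
  PA = list(layerSpec(45, 45, sigma_depth = 30, peak_sv = -63.5,
                      persistent = TRUE),
            layerSpec(420, 70, sigma_depth = 35, peak_sv = -64),
            layerSpec(350, 350, sigma_depth = 45, peak_sv = -66,
                      persistent = TRUE, diel_presence = "day_only")))

.ANCHORS <- list(AT = c(lat = 22, lon = -25), SA = c(lat = 25, lon = -55),
                 PA = c(lat = 7, lon = -85))

#' Built-in regional scene presets
#'
#' Returns the regime of one of three contrasting tropical regions: `"AT"`
#' (Eastern Tropical North Atlantic), `"SA"` (Sargasso Sea) or `"PA"`
#' (Eastern Tropical Pacific). Each preset bundles the scattering-layer
#' configuration, an acoustic noise floor of -85 dB (well below the -70 dB
#' extraction threshold), hydrographic profile parameters and a geographic
#' anchor. Any component can be overridden.
#'
#' @param name `"AT"`, `"SA"` or `"PA"`.
#' @param layers optional list of [LayerSpec] replacing the regional default.
#' @param noise_floor_sv scene noise floor (dB).
#' @param ctd_params named list merged over the regional hydrography.
#' @param lat,lon anchor position override (decimal degrees).
#' @return a [RegionPreset].
#' @export
#' @examples
#' regionPreset("PA")
regionPreset <- function(name = c("AT", "SA", "PA"), layers = NULL,
                         noise_floor_sv = -85, ctd_params = list(),
                         lat = NULL, lon = NULL) {
  name <- match.arg(name)
  anchor <- .ANCHORS[[name]]
  new("RegionPreset", name = name,
      layers = if (is.null(layers)) .LAYER_REGIMES[[name]] else layers,
      noise_floor_sv = noise_floor_sv,
      ctd_params = utils::modifyList(.CTD_REGIMES[[name]], ctd_params),
      lat = if (is.null(lat)) unname(anchor["lat"]) else lat,
      lon = if (is.null(lon)) unname(anchor["lon"]) else lon)
}
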