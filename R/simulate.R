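#' Simulate a dual-use echogram scene
#'
#' Builds an [Echogram] in which every configured layer contributes a
#' Gaussian-in-depth Sv bump whose centre moves smoothly between its daytime
#' and night-time depths, driven by the solar altitude at each ping through a
#' logistic ramp (centred on the horizon, 6 degree scale), so crepuscular
#' ascents and descents are gradual. Layer contributions and the noise floor
#' combine in the linear intensity domain; independent Gaussian dB jitter is
#' applied to each layer's peak term per ping. The ship steams from the
#' preset anchor on a fixed heading. Deterministic for a given seed.
#'
#' @param preset a [RegionPreset].
#' @param frequency_khz acoustic frequency label (kHz).
#' @param start POSIXct (UTC) first ping time.
#' @param duration_hours record length.
#' @param ping_interval_s seconds between pings.
#' @param depth_max deepest sample (m); must cover the deepest configured
#'   layer centre.
#' @param seed integer RNG seed.
#' @param depth_bin_m vertical sample spacing (m).
#' @param speed_kn ship speed (knots).
#' @param heading_deg course over ground (degrees clockwise from north).
#' @return an [Echogram].
#' @export
#' @examples
#' eg <- generateEchogram(regionPreset("AT"), 38,
#'                        as.POSIXct("2021-12-15 10:00:00", tz = "UTC"),
#'                        duration_hours = 1, ping_interval_s = 60,
#'                        depth_max = 800, seed = 1)
generateEchogram <- function(preset, frequency_khz, start, duration_hours,
                             ping_interval_s = 30, depth_max = 800, seed = 1,
                             depth_bin_m = 1, speed_kn = 10,
                             heading_deg = 270) {
  stopifnot(is(preset, "RegionPreset"))
  deepest <- if (length(preset@layers))
    max(vapply(preset@layers, function(l)
      max(l@day_center_depth, l@night_center_depth), numeric(1))) else 0
  if (depth_max < deepest)
    stop(sprintf("depth_max (%g m) is shallower than the deepest configured layer (%g m)",
                 depth_max, deepest))
  start <- .asUTC(start)
  times <- start + seq(0, duration_hours * 3600 - 1e-9, by = ping_interval_s)
  n <- length(times)
  step_nmi <- speed_kn * ping_interval_s / 3600
  h <- heading_deg * pi / 180
  lat <- preset@lat + cumsum(c(0, rep(step_nmi * cos(h) / 60, n - 1)))
  lon <- preset@lon +
    cumsum(c(0, rep(step_nmi * sin(h), n - 1)) / (60 * cos(lat * pi / 180)))
  depths <- seq(depth_bin_m / 2, depth_max - depth_bin_m / 2, by = depth_bin_m)

  alt <- solarAltitude(times, lat, lon)
  set.seed(.deriveSeed(seed, paste0("echogram-", preset@name, "-", frequency_khz)))
  linear <- matrix(10^(preset@noise_floor_sv / 10), length(depths), n)
  for (l in preset@layers) {
    centre <- if (l@persistent) rep(l@day_center_depth, n)
      else l@day_center_depth +
        (l@night_center_depth - l@day_center_depth) * stats::plogis(-alt / 6)
    presence <- switch(l@diel_presence,
                       always = rep(1, n),
                       day_only = stats::plogis(alt / 6),
                       night_only = stats::plogis(-alt / 6))
    peak <- l@peak_sv + stats::rnorm(n, 0, l@sv_jitter_sd)
    shape <- exp(-outer(depths, centre, "-")^2 / (2 * l@sigma_depth^2))
    linear <- linear + shape *
      rep(10^(peak / 10) * presence, each = length(depths))
  }
  Echogram(10 * log10(linear), depths, times, lat, lon, frequency_khz)
}

#' Analytic hydrographic profiles of a preset
#'
#' The noise-free vertical structure the CTD generator is built on:
#' a warm mixed layer over a tanh thermocline, a tanh halocline, a
#' Gaussian-shaped oxygen minimum zone reaching the configured minimum, a
#' subsurface Gaussian chlorophyll maximum over a small background, and
#' exponentially attenuated PAR.
#'
#' @param preset a [RegionPreset].
#' @param depths numeric depths (m).
#' @return data.frame with `depth_m` and the five profile variables.
#' @export
ctdAnalyticProfile <- function(preset, depths) {
  p <- preset@ctd_params
  tscale <- max(20, 0.2 * p$thermocline_depth_m)
  hscale <- max(20, 0.2 * p$halocline_depth_m)
  temperature <- p$deep_temp_c + (p$surface_temp_c - p$deep_temp_c) / 2 *
    (1 - tanh((depths - p$thermocline_depth_m) / tscale))
  salinity <- p$deep_salinity_psu +
    (p$surface_salinity_psu - p$deep_salinity_psu) / 2 *
    (1 - tanh((depths - p$halocline_depth_m) / hscale))
  oxygen <- p$surface_oxygen - (p$surface_oxygen - p$omz_min_oxygen) *
    exp(-(depths - p$omz_core_depth_m)^2 / (2 * p$omz_width_m^2))
  chlorophyll_a <- 0.02 + p$surface_chl *
    exp(-(depths - p$chl_max_depth_m)^2 / (2 * p$chl_width_m^2))
  par <- p$par_surface * exp(-p$par_attenuation_m * depths)
  data.frame(depth_m = depths, temperature = temperature, salinity = salinity,
             oxygen = oxygen, chlorophyll_a = chlorophyll_a, par = par)
}

#' Simulate CTD stations for a preset
#'
#' Stations are laid out along-track westward of the preset anchor, cast
#' times alternating between local midday and local night. Profiles are the
#' analytic regional forms of [ctdAnalyticProfile()] plus small seeded
#' Gaussian noise scaled by `noise_scale` (0 gives the exact analytic
#' profiles). Oxygen, chlorophyll and PAR are clamped at zero.
#'
#' @param preset a [RegionPreset].
#' @param n_stations number of stations (>= 1).
#' @param seed integer RNG seed.
#' @param depth_max,depth_step_m profile extent and resolution (m).
#' @param noise_scale multiplier on the per-variable noise standard
#'   deviations (0.1 degC, 0.02 PSU, 2 umol/kg, 0.02 ug/m^3, 2% of PAR).
#' @param date base UTC date for cast times.
#' @return list of [CTDStation].
#' @export
generateCTD <- function(preset, n_stations, seed = 1, depth_max = 1000,
                        depth_step_m = 5, noise_scale = 1,
                        date = as.Date("2021-12-15")) {
  stopifnot(is(preset, "RegionPreset"), n_stations >= 1)
  if (preset@ctd_params$omz_min_oxygen < 0)
    stop("non-physical preset: omz_min_oxygen must be >= 0")
  set.seed(.deriveSeed(seed, paste0("ctd-", preset@name)))
  depths <- seq(depth_step_m, depth_max, by = depth_step_m)
  base <- ctdAnalyticProfile(preset, depths)
  lapply(seq_len(n_stations), function(i) {
    lon <- preset@lon - 0.2 * (i - 1)
    lat <- preset@lat
    # alternate local-midday / local-night casts; local solar time ~ UTC + lon/15 h
    local_hour <- if (i %% 2 == 1) 13 else 1
    time <- as.POSIXct(paste(date + (i - 1) %/% 2, "00:00:00"), tz = "UTC") +
      (local_hour - lon / 15) * 3600
    prof <- base
    nz <- length(depths)
    prof$temperature <- prof$temperature + noise_scale * stats::rnorm(nz, 0, 0.1)
    prof$salinity <- prof$salinity + noise_scale * stats::rnorm(nz, 0, 0.02)
    prof$oxygen <- pmax(0, prof$oxygen + noise_scale * stats::rnorm(nz, 0, 2))
    prof$chlorophyll_a <- pmax(0, prof$chlorophyll_a +
                                 noise_scale * stats::rnorm(nz, 0, 0.02))
    prof$par <- pmax(0, prof$par * (1 + noise_scale * stats::rnorm(nz, 0, 0.02)))
    CTDStation(sprintf("%s-%02d", preset@name, i), lat, lon, time, prof)
  })
}

# Regional descriptor regimes for the per-day sampler: minimum depth, width
# and mean Sv per frequency. The Pacific has the shallowest (~10 m) and
# thickest (~150/120 m) layers with the strongest backscatter (~ -63.5 dB);
# the Sargasso the thinnest (~115/100 m) and weakest (~ -67 dB); the
# Atlantic the deepest layers (maximum depth ~400 m).
.DESCRIPTOR_REGIMES <- list(
  PA = list(min_depth = 10, width_18 = 150, width_38 = 120,
            sv_18 = -63, sv_38 = -64),
  SA = list(min_depth = 60, width_18 = 115, width_38 = 100,
            sv_18 = -67, sv_38 = -67),
  AT = list(min_depth = 270, width_18 = 130, width_38 = 130,
            sv_18 = -65, sv_38 = -65))

.DESCRIPTOR_SD <- c(min_depth = 5, width = 10, sv = 0.8, lon = 1.5, lat = 1)

#' Sample per-day layer descriptor vectors with known region labels
#'
#' Draws dual-frequency descriptor vectors (minimum depth, maximum depth,
#' width and mean Sv at 18 and 38 kHz, plus longitude and latitude) from
#' region-specific normal distributions whose means follow the regional
#' regimes above; maximum depth is minimum plus width. True region labels
#' are retained for recovery tests of the clustering stage.
#'
#' @param presets list of [RegionPreset] (>= 2) naming the regions to draw.
#' @param n_per_region samples per region (>= 2).
#' @param seed integer RNG seed.
#' @param spread multiplier on the regime standard deviations; 0 collapses
#'   every vector onto its region mean.
#' @return data.frame of descriptors with a `region` column.
#' @export
generateDescriptorSamples <- function(presets, n_per_region, seed = 1,
                                      spread = 1) {
  if (length(presets) < 2) stop("at least two region presets are required")
  if (n_per_region < 2) stop("n_per_region must be >= 2")
  set.seed(.deriveSeed(seed, "descriptors"))
  out <- lapply(presets, function(pr) {
    stopifnot(is(pr, "RegionPreset"))
    rg <- .DESCRIPTOR_REGIMES[[pr@name]]
    if (is.null(rg)) stop("no descriptor regime for region ", pr@name)
    s <- .DESCRIPTOR_SD * spread
    n <- n_per_region
    min18 <- pmax(1, stats::rnorm(n, rg$min_depth, s["min_depth"]))
    min38 <- pmax(1, stats::rnorm(n, rg$min_depth, s["min_depth"]))
    w18 <- pmax(5, stats::rnorm(n, rg$width_18, s["width"]))
    w38 <- pmax(5, stats::rnorm(n, rg$width_38, s["width"]))
    data.frame(region = pr@name,
               min_depth_18 = min18, max_depth_18 = min18 + w18,
               width_18 = w18, mean_sv_18 = stats::rnorm(n, rg$sv_18, s["sv"]),
               min_depth_38 = min38, max_depth_38 = min38 + w38,
               width_38 = w38, mean_sv_38 = stats::rnorm(n, rg$sv_38, s["sv"]),
               lon = stats::rnorm(n, pr@lon, s["lon"]),
               lat = stats::rnorm(n, pr@lat, s["lat"]))
  })
  do.call(rbind, out)
}
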