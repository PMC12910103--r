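#' Geometric solar altitude
#'
#' NOAA solar-calculator ephemeris (the Julian-century formulation of
#' Meeus): geometric mean longitude and anomaly of the sun, equation of
#' centre, apparent longitude and corrected obliquity give the declination
#' and equation of time; the hour angle follows from true solar time at the
#' given longitude and the altitude from the spherical triangle.
#' Atmospheric refraction is ignored — irrelevant at the +-18 degree
#' thresholds used for diel classification. Accuracy is a few hundredths of
#' a degree over the satellite era.
#'
#' @param time POSIXct (UTC), vectorised.
#' @param lat,lon position in decimal degrees (east-positive longitude).
#' @return altitude above the horizon, degrees.
#' @export
#' @examples
#' solarAltitude(as.POSIXct("2021-03-21 12:00:00", tz = "UTC"), 0, 0)
solarAltitude <- function(time, lat, lon) {
  stopifnot(all(abs(lat) <= 90))
  time <- .asUTC(time)
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(gmas * rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * rad) * 0.000289
  omega <- 125.04 - 1934.136 * jc
  applong <- gmls + eqctr - 0.00569 - 0.00478 * sin(omega * rad)
  mobliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos(omega * rad)
  decl <- asin(sin(obliq * rad) * sin(applong * rad))
  vary <- tan(obliq / 2 * rad)^2
  eqtime <- 4 / rad * (vary * sin(2 * gmls * rad) -
    2 * eeo * sin(gmas * rad) +
    4 * eeo * vary * sin(gmas * rad) * cos(2 * gmls * rad) -
    0.5 * vary^2 * sin(4 * gmls * rad) -
    1.25 * eeo^2 * sin(2 * gmas * rad))
  frac_min <- (jd + 0.5 - floor(jd + 0.5)) * 1440   # minutes past UTC midnight
  tst <- (frac_min + eqtime + 4 * lon) %% 1440      # true solar time
  ha <- (tst / 4 - 180) * rad
  latr <- lat * rad
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cosz))) / rad
}

#' Classify solar altitude into diel phases
#'
#' Day is altitude strictly above `+threshold_deg`, night strictly below
#' `-threshold_deg`; everything between (boundary values included) is the
#' crepuscular `transition`, which diel analyses exclude. The default 18
#' degrees is the astronomical-twilight bound.
#'
#' @param altitude degrees above the horizon (vectorised).
#' @param threshold_deg diel bound, degrees.
#' @return character vector in `c("day", "night", "transition")`.
#' @export
classifyDiel <- function(altitude, threshold_deg = 18) {
  ifelse(altitude > threshold_deg, "day",
         ifelse(altitude < -threshold_deg, "night", "transition"))
}

#' Day and night mean vertical profiles and their difference
#'
#' Per depth bin, the linear-domain mean Sv over day columns and over night
#' columns (transition columns excluded), and the night-minus-day difference
#' in dB — the standard picture of diel vertical migration: positive above
#' the migration midpoint, negative below, for an upward night migration.
#'
#' @param g an [IntegrationGrid].
#' @param diel per-column diel labels; computed from column time/position
#'   when omitted.
#' @param domain `"linear"` (default, energy-consistent) or `"db"` averaging.
#' @return data.frame with depth_m, mean_sv_day, mean_sv_night, delta_db,
#'   n_day, n_night; bins with no non-missing cells in a phase are `NA`.
#' @export
meanProfiles <- function(g, diel = NULL, domain = c("linear", "db")) {
  domain <- match.arg(domain)
  if (is.null(diel)) diel <- .columnDiel(g)
  stopifnot(length(diel) == ncol(g))
  if (!any(diel == "day") || !any(diel == "night"))
    stop("need at least one day and one night column")
  sv <- svMatrix(g)
  phase_mean <- function(cols) {
    m <- sv[, cols, drop = FALSE]
    if (domain == "linear") apply(m, 1, .meanDb)
    else rowMeans(m, na.rm = TRUE)
  }
  day <- phase_mean(diel == "day")
  night <- phase_mean(diel == "night")
  data.frame(depth_m = depthAxis(g), mean_sv_day = day, mean_sv_night = night,
             delta_db = night - day,
             n_day = rowSums(!is.na(sv[, diel == "day", drop = FALSE])),
             n_night = rowSums(!is.na(sv[, diel == "night", drop = FALSE])))
}

#' Weighted mean depth of a backscatter column
#'
#' The backscatter-weighted mean of bin-centre depths,
#' \eqn{\mathrm{WMD} = \sum_i z_i s_i / \sum_i s_i} with \eqn{s_i} the linear
#' backscatter — a proxy for the depth of greatest acoustic density. Missing
#' cells are excluded; with `threshold_db` set, only cells at or above the
#' threshold contribute. Invariant under any constant dB offset.
#'
#' @param sv numeric vector of Sv (dB) for one column.
#' @param depths bin-centre depths (m), same length.
#' @param threshold_db optional restriction to cells `>= threshold_db`.
#' @return WMD in metres, or `NA` if no cell qualifies.
#' @export
computeWMD <- function(sv, depths, threshold_db = NULL) {
  stopifnot(length(sv) == length(depths))
  keep <- !is.na(sv)
  if (!is.null(threshold_db)) keep <- keep & sv >= threshold_db
  if (!any(keep)) return(NA_real_)
  s <- dbToLinear(sv[keep])
  sum(depths[keep] * s) / sum(s)
}

#' Per-column weighted mean depth series
#'
#' @param g an [IntegrationGrid].
#' @param threshold_db passed to [computeWMD()].
#' @return data.frame with time, lat, lon and wmd_m per column.
#' @export
wmdSeries <- function(g, threshold_db = NULL) {
  sv <- svMatrix(g)
  d <- depthAxis(g)
  pos <- pingPositions(g)
  data.frame(time = pingTimes(g), lat = pos$lat, lon = pos$lon,
             wmd_m = apply(sv, 2, computeWMD, depths = d,
                           threshold_db = threshold_db))
}

#' Cross-frequency validation of vertical migration
#'
#' Confirms that migration seen at one frequency is biological rather than a
#' resonance artefact: Pearson correlation between the paired 18 and 38 kHz
#' WMD series on their common columns, plus the diel migration amplitude
#' (mean night WMD minus mean day WMD) at each frequency.
#'
#' @param wmd18,wmd38 WMD series from [wmdSeries()] on aligned grids.
#' @param diel per-column diel labels shared by both series.
#' @return list with `pearson_r`, `amplitude_day_night_18`,
#'   `amplitude_day_night_38` and `n` (paired columns).
#' @export
crossFrequencyValidation <- function(wmd18, wmd38, diel) {
  stopifnot(nrow(wmd18) == nrow(wmd38), length(diel) == nrow(wmd18))
  ok <- !is.na(wmd18$wmd_m) & !is.na(wmd38$wmd_m)
  if (sum(ok) < 3) stop("need at least 3 paired WMD values")
  r <- if (stats::sd(wmd18$wmd_m[ok]) == 0 || stats::sd(wmd38$wmd_m[ok]) == 0) {
    warning("zero variance in a WMD series: correlation undefined")
    NA_real_
  } else stats::cor(wmd18$wmd_m[ok], wmd38$wmd_m[ok])
  amp <- function(w) mean(w$wmd_m[diel == "night"], na.rm = TRUE) -
    mean(w$wmd_m[diel == "day"], na.rm = TRUE)
  list(pearson_r = r, amplitude_day_night_18 = amp(wmd18),
       amplitude_day_night_38 = amp(wmd38), n = sum(ok))
}
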