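.TIME_FMT <- "%Y-%m-%dT%H:%M:%OS3Z"

.fmtTime <- function(t) format(.asUTC(t), .TIME_FMT, tz = "UTC")

.parseTime <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(t)) stop("unparseable ISO-8601 timestamp(s): ",
                     paste(utils::head(x[is.na(t)], 3), collapse = ", "))
  t
}

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read an echogram from disk
#'
#' Two plain-text dialects are supported. `"long_csv"` (canonical) has one
#' row per sample with columns `ping_time` (ISO-8601 UTC), `lat`, `lon`,
#' `depth_m`, `sv_db` and optionally `frequency_khz`. `"wide_csv"` is the
#' bulk gridded container: a depth-by-ping Sv matrix CSV whose first column
#' is `depth_m`, with per-ping time/position in a `<path>.meta.csv` sidecar.
#' Empty `sv_db` entries become missing values.
#'
#' @param path file path.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @param frequency_khz frequency to record when the file carries none.
#' @return an [Echogram].
#' @seealso [writeEchogram()]
#' @export
readEchogram <- function(path, dialect = c("long_csv", "wide_csv"),
                         frequency_khz = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "long_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .requireCols(df, c("ping_time", "lat", "lon", "depth_m", "sv_db"),
                 basename(path))
    if (is.null(frequency_khz)) {
      if (!"frequency_khz" %in% names(df))
        stop("frequency_khz: neither a column nor an argument")
      frequency_khz <- df$frequency_khz[1]
    }
    df$ping_time <- .parseTime(df$ping_time)
    pings <- unique(df[, c("ping_time", "lat", "lon")])
    pings <- pings[order(pings$ping_time), , drop = FALSE]
    depths <- sort(unique(df$depth_m))
    if (length(depths) > 1 && diff(range(diff(depths))) > 1e-6 * mean(diff(depths)))
      stop("depth axis is not monotone with uniform step")
    sv <- matrix(NA_real_, length(depths), nrow(pings))
    i <- match(df$depth_m, depths)
    j <- match(paste(df$ping_time, df$lat, df$lon),
               paste(pings$ping_time, pings$lat, pings$lon))
    sv[cbind(i, j)] <- df$sv_db
    Echogram(sv, depths, pings$ping_time, pings$lat, pings$lon, frequency_khz)
  } else {
    meta_path <- paste0(path, ".meta.csv")
    if (!file.exists(meta_path)) stop("no such file: ", meta_path)
    wide <- utils::read.csv(path, check.names = FALSE)
    .requireCols(wide, "depth_m", basename(path))
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    .requireCols(meta, c("ping_time", "lat", "lon"), basename(meta_path))
    sv <- as.matrix(wide[, -match("depth_m", names(wide)), drop = FALSE])
    if (ncol(sv) != nrow(meta))
      stop("wide matrix has ", ncol(sv), " pings but sidecar has ", nrow(meta))
    if (is.null(frequency_khz)) {
      if (!"frequency_khz" %in% names(meta))
        stop("frequency_khz: neither in sidecar nor an argument")
      frequency_khz <- meta$frequency_khz[1]
    }
    Echogram(sv, wide$depth_m, .parseTime(meta$ping_time), meta$lat, meta$lon,
             frequency_khz)
  }
}

#' Write an echogram to disk
#'
#' Inverse of [readEchogram()]; round-trips Sv to better than 1e-6 dB.
#'
#' @param e an [Echogram].
#' @param path destination file.
#' @param dialect `"long_csv"` or `"wide_csv"` (matrix CSV + metadata sidecar).
#' @return `path`, invisibly.
#' @export
writeEchogram <- function(e, path, dialect = c("long_csv", "wide_csv")) {
  dialect <- match.arg(dialect)
  sv <- svMatrix(e)
  pos <- pingPositions(e)
  if (dialect == "long_csv") {
    df <- data.frame(
      ping_time = rep(.fmtTime(pingTimes(e)), each = nrow(sv)),
      lat = rep(pos$lat, each = nrow(sv)),
      lon = rep(pos$lon, each = nrow(sv)),
      depth_m = rep(depthAxis(e), ncol(sv)),
      sv_db = as.vector(sv),
      frequency_khz = frequencyKHz(e))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    wide <- data.frame(depth_m = depthAxis(e), sv,
                       check.names = FALSE)
    names(wide)[-1] <- sprintf("ping%05d", seq_len(ncol(sv)))
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    meta <- data.frame(ping = sprintf("ping%05d", seq_len(ncol(sv))),
                       ping_time = .fmtTime(pingTimes(e)),
                       lat = pos$lat, lon = pos$lon,
                       frequency_khz = frequencyKHz(e))
    utils::write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

.LAYER_COLS <- c("layer_id", "frequency_khz", "date", "min_depth_m",
                 "max_depth_m", "width_m", "length_m", "mean_sv_db", "diel")

#' Write and read a scattering-layer descriptor table
#'
#' One CSV row per layer: identifier, frequency, date, depth band, width,
#' along-track length, linear-domain mean Sv and diel label. Member-cell
#' index sets are an in-memory attribute and are not serialized.
#'
#' @param layers a layer table as returned by [extractLayers()].
#' @param path destination CSV.
#' @return `writeLayers()` returns `path` invisibly; `readLayers()` the table.
#' @export
writeLayers <- function(layers, path) {
  df <- as.data.frame(layers)[, intersect(.LAYER_COLS, names(layers)), drop = FALSE]
  for (nm in setdiff(.LAYER_COLS, names(df))) df[[nm]] <- logical(0)
  utils::write.csv(df[.LAYER_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLayers
#' @export
readLayers <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(date = "character"))
  .requireCols(df, .LAYER_COLS, basename(path))
  df
}

#' Write and read CTD stations as long CSV
#'
#' One row per (station, depth): station metadata plus the five profile
#' variables and optional turbidity.
#'
#' @param stations list of [CTDStation] objects.
#' @param path destination CSV.
#' @return `writeCTDStations()` returns `path` invisibly; `readCTDStations()`
#'   a list of [CTDStation].
#' @export
writeCTDStations <- function(stations, path) {
  rows <- lapply(stations, function(s) {
    p <- ctdProfile(s)
    cbind(data.frame(station_id = s@station_id, lat = s@lat, lon = s@lon,
                     time = .fmtTime(s@time)), p)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCTDStations
#' @export
readCTDStations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("station_id", "lat", "lon", "time", "depth_m", .ctdVars),
               basename(path))
  lapply(split(df, df$station_id), function(d) {
    prof_cols <- setdiff(names(d), c("station_id", "lat", "lon", "time"))
    CTDStation(d$station_id[1], d$lat[1], d$lon[1], .parseTime(d$time[1]),
               d[order(d$depth_m), prof_cols, drop = FALSE])
  })
}
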