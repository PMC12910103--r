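# Independent oracles: each re-derives a quantity by a different route than
# the implementation (recursive flood fill vs two-pass labelling, PSA vs
# NOAA ephemeris, direct formulas vs library calls, exhaustive enumeration
# vs greedy/iterative algorithms).

options(echoscape.verbose = FALSE)

# --- recursive flood fill, 4-connectivity ------------------------------------
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      if (i < 1 || j < 1 || i > nr || j > nc) next
      if (!mask[i, j] || lab[i, j] != 0L) next
      lab[i, j] <- cur
      stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
    }
  }
  lab
}

# number of distinct (a,b) label co-occurrence classes agree up to relabelling
same_partition <- function(a, b) {
  pos <- a > 0 | b > 0
  if (!all((a > 0) == (b > 0))) return(FALSE)
  key <- paste(a[a > 0], b[b > 0])
  length(unique(key)) == max(a) && max(a) == max(b)
}

# --- PSA solar ephemeris (Blanco-Muriel et al. 2001) -------------------------
oracle_solar_altitude <- function(time, lat, lon) {
  idiv <- function(a, b) trunc(a / b)
  lt <- as.POSIXlt(time, tz = "UTC")
  year <- lt$year + 1900; month <- lt$mon + 1; day <- lt$mday
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  jd <- idiv(1461 * (year + 4800 + idiv(month - 14, 12)), 4) +
    idiv(367 * (month - 2 - 12 * idiv(month - 14, 12)), 12) -
    idiv(3 * idiv(year + 4900 + idiv(month - 14, 12), 100), 4) +
    day - 32075 - 0.5 + hour / 24
  n <- jd - 2451545.0
  Omega <- 2.1429 - 0.0010394594 * n
  L <- 4.8950630 + 0.017202791698 * n
  g <- 6.2400600 + 0.0172019699 * n
  l <- L + 0.03341607 * sin(g) + 0.00034894 * sin(2 * g) - 0.0001134 -
    0.0000203 * sin(Omega)
  ep <- 0.4090928 - 6.2140e-9 * n + 0.0000396 * cos(Omega)
  ra <- atan2(cos(ep) * sin(l), cos(l)) %% (2 * pi)
  dec <- asin(sin(ep) * sin(l))
  gmst <- 6.6974243242 + 0.0657098283 * n + hour
  lmst <- (gmst * 15 + lon) * pi / 180
  ha <- lmst - ra
  latr <- lat * pi / 180
  cosz <- cos(latr) * cos(ha) * cos(dec) + sin(dec) * sin(latr)
  zen <- acos(pmin(1, pmax(-1, cosz)))
  zen <- zen + (6371.01 / 149597890) * sin(zen)   # parallax
  90 - zen * 180 / pi
}

# --- O(n^2) silhouette from the definition -----------------------------------
oracle_mean_silhouette <- function(labels, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else NA
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# --- spherical law of cosines distance (nmi), R = 6371 km --------------------
oracle_dist_nmi <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371000 * acos(pmin(1, pmax(-1, ca))) / 1852
}

# --- exhaustive best 2-partition by within-cluster sum of squares ------------
oracle_best_2partition <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {    # fix point 1 in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2) next
    ss <- sum(vapply(split(seq_len(n), lab), function(idx) {
      sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
    }, numeric(1)))
    if (ss < best_ss) { best_ss <- ss; best <- lab }
  }
  list(labels = best, ss = best_ss)
}

# --- brute-force maximum-overlap layer assignment ----------------------------
oracle_max_overlap_pairs <- function(jmat, jmin) {
  # enumerate all one-to-one assignments, maximise total Jaccard over pairs
  n1 <- nrow(jmat); n2 <- ncol(jmat)
  best <- list(); best_tot <- -1
  assignments <- function(is, js, acc, tot) {
    # try closing here
    if (tot > best_tot) { best_tot <<- tot; best <<- acc }
    for (i in is) for (j in js) {
      if (jmat[i, j] >= jmin)
        assignments(setdiff(is, i), setdiff(js, j),
                    c(acc, list(c(i, j))), tot + jmat[i, j])
    }
  }
  assignments(seq_len(n1), seq_len(n2), list(), 0)
  best
}

# --- shared scene builders ---------------------------------------------------
make_day_grid <- function(preset = regionPreset("AT"), freq = 38,
                          start = "2021-12-15 12:00:00", hours = 2,
                          ping_s = 30, seed = 2, offset = 10) {
  eg <- generateEchogram(preset, freq, as.POSIXct(start, tz = "UTC"),
                         duration_hours = hours, ping_interval_s = ping_s,
                         depth_max = 800, seed = seed)
  echoIntegrate(applySurfaceOffset(eg, offset))
}

tiny_echogram <- function(sv = matrix(c(-70, -65, -80, -71, -66, -81), 3, 2),
                          lat = c(28, 28.001), lon = c(-15.5, -15.5)) {
  Echogram(sv, depth_m = c(10.5, 11.5, 12.5),
           ping_time = as.POSIXct("2021-12-11 13:00:00", tz = "UTC") + c(0, 10),
           lat = lat, lon = lon, frequency_khz = 38)
}
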