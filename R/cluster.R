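# z-score each column. Constant columns carry no clustering information:
# rejected by default, or centred to zero when tolerated (short transects can
# legitimately hold e.g. latitude fixed).
.zscore <- function(m, allow_constant = FALSE) {
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    if (!allow_constant)
      stop("constant descriptor column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    .log("constant descriptor column(s) centred to zero: %s",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  out <- scale(m, center = TRUE, scale = ifelse(sds == 0, 1, sds))
  out[, , drop = FALSE]
}

#' Build the seascape descriptor matrix
#'
#' Assembles, per cluster unit, the dual-frequency descriptor vector fed to
#' k-means: mean minimum depth, maximum depth, width and mean Sv at each
#' frequency plus mean longitude and latitude (10 columns). The default unit
#' is the calendar day — each surveyed day becomes one row, aggregating its
#' matched layer pairs (Sv aggregated in the linear domain) — with
#' `"per_layer"` (one row per matched pair) as the alternative. Rows with
#' any missing descriptor are dropped with a logged count.
#'
#' @param layers18,layers38 layer tables from [extractLayers()].
#' @param pairs matched pairs from [matchFrequencies()] (`$pairs`).
#' @param unit `"per_day"` or `"per_layer"`.
#' @return list with `X` (standardized matrix), `raw` (unstandardized
#'   descriptors with unit metadata) and `unit`.
#' @export
buildDescriptorMatrix <- function(layers18, layers38,
                                  pairs, unit = c("per_day", "per_layer")) {
  unit <- match.arg(unit)
  if (!nrow(pairs)) stop("no matched layer pairs")
  i <- match(pairs$id18, layers18$layer_id)
  j <- match(pairs$id38, layers38$layer_id)
  rec <- data.frame(
    date = layers18$date[i],
    min_depth_18 = layers18$min_depth_m[i], max_depth_18 = layers18$max_depth_m[i],
    width_18 = layers18$width_m[i], mean_sv_18 = layers18$mean_sv_db[i],
    min_depth_38 = layers38$min_depth_m[j], max_depth_38 = layers38$max_depth_m[j],
    width_38 = layers38$width_m[j], mean_sv_38 = layers38$mean_sv_db[j],
    lon = (layers18$lon[i] + layers38$lon[j]) / 2,
    lat = (layers18$lat[i] + layers38$lat[j]) / 2)
  if (unit == "per_day") {
    agg <- lapply(split(rec, rec$date), function(d) {
      out <- d[1, , drop = FALSE]
      for (nm in setdiff(names(d), c("date", "mean_sv_18", "mean_sv_38")))
        out[[nm]] <- mean(d[[nm]])
      out$mean_sv_18 <- .meanDb(d$mean_sv_18)
      out$mean_sv_38 <- .meanDb(d$mean_sv_38)
      out
    })
    rec <- do.call(rbind, agg)
  }
  complete <- stats::complete.cases(rec)
  if (any(!complete))
    .log("dropped %d unit(s) with missing descriptors", sum(!complete))
  rec <- rec[complete, , drop = FALSE]
  if (nrow(rec) < 2) stop("fewer than 2 cluster units")
  rownames(rec) <- NULL
  X <- .zscore(as.matrix(rec[, setdiff(names(rec), "date")]),
               allow_constant = TRUE)
  list(X = X, raw = rec, unit = unit)
}

#' K-means clustering of descriptor vectors
#'
#' Thin deterministic wrapper around `stats::kmeans` (the standard k-means
#' of the R stats package): best of `n_init` restarts under a fixed seed,
#' up to 300 iterations. An initialisation that leaves a cluster empty is
#' re-seeded with a logged note.
#'
#' @param X numeric matrix (rows = units), normally standardized.
#' @param k number of clusters (>= 2, < rows).
#' @param seed integer seed; identical calls give identical labels.
#' @param n_init random restarts.
#' @return list with `labels`, `centroids` and `inertia` (total
#'   within-cluster sum of squares).
#' @export
kmeansCluster <- function(X, k, seed = 1, n_init = 20) {
  X <- as.matrix(X)
  stopifnot(k >= 2, nrow(X) > k)
  for (attempt in 0:4) {
    set.seed(.deriveSeed(seed, sprintf("kmeans-%d-%d", k, attempt)))
    fit <- tryCatch(stats::kmeans(X, centers = k, nstart = n_init,
                                  iter.max = 300),
                    error = function(e) e)
    if (!inherits(fit, "error"))
      return(list(labels = unname(fit$cluster), centroids = fit$centers,
                  inertia = fit$tot.withinss))
    .log("k-means initialisation produced an empty cluster; re-seeding (%s)",
         conditionMessage(fit))
  }
  stop("k-means failed after 5 re-seeded attempts: ", conditionMessage(fit))
}

# Mean silhouette width of a labelled clustering (cluster::silhouette).
.meanSilhouette <- function(labels, X) {
  mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
}

#' Select the number of clusters by mean silhouette width
#'
#' Runs [kmeansCluster()] for every k in `k_range` and scores each
#' clustering by its mean silhouette width (the balance of within-cluster
#' cohesion against separation from the nearest other cluster); the k with
#' the largest mean silhouette wins, ties going to the smallest k
#' (parsimony).
#'
#' @param X numeric matrix, standardized descriptor rows.
#' @param k_range `c(min, max)` inclusive candidate interval, min >= 2;
#'   requires `nrow(X) >= max(k_range) + 1`.
#' @param seed integer seed.
#' @param n_init k-means restarts per k.
#' @return list with `k` (selected) and `silhouette_by_k` (named numeric).
#' @export
selectKSilhouette <- function(X, k_range = c(2, 8), seed = 1, n_init = 20) {
  X <- as.matrix(X)
  ks <- seq(k_range[1], k_range[2])
  stopifnot(ks[1] >= 2)
  if (nrow(X) < max(ks) + 1)
    stop("need at least max(k_range) + 1 rows")
  if (all(apply(X, 2, stats::sd) == 0))
    stop("degenerate descriptor matrix: all rows equal")
  sil <- vapply(ks, function(k)
    .meanSilhouette(kmeansCluster(X, k, seed, n_init)$labels, X), numeric(1))
  names(sil) <- ks
  list(k = ks[which.max(sil)], silhouette_by_k = sil)
}

#' Five-number summaries of raw descriptors per cluster
#'
#' Per cluster and descriptor: minimum, lower quartile, median, upper
#' quartile, maximum (type-7 quantiles) and the count of Tukey outliers
#' (beyond 1.5 IQR from the quartiles) — the numbers a descriptor boxplot
#' displays.
#'
#' @param labels integer cluster labels.
#' @param raw data.frame of unstandardized numeric descriptors.
#' @return long data.frame: cluster, descriptor, min, q1, median, q3, max,
#'   n_outliers, n.
#' @export
summarizeClusters <- function(labels, raw) {
  raw <- as.data.frame(raw)
  num <- names(raw)[vapply(raw, is.numeric, logical(1))]
  if (!length(labels) || length(labels) != nrow(raw))
    stop("labels must match descriptor rows")
  if (any(tabulate(labels, max(labels)) == 0)) stop("empty cluster")
  rows <- list()
  for (cl in sort(unique(labels))) {
    for (v in num) {
      x <- raw[[v]][labels == cl]
      q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
      iqr <- q[4] - q[2]
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, descriptor = v, min = q[1], q1 = q[2], median = q[3],
        q3 = q[4], max = q[5],
        n_outliers = sum(x < q[2] - 1.5 * iqr | x > q[4] + 1.5 * iqr),
        n = length(x))
    }
  }
  do.call(rbind, rows)
}

#' Classify pelagic seascapes
#'
#' The full clustering stage: standardize the descriptors, select k by mean
#' silhouette width over `k_range`, fit the final k-means, and summarise
#' each cluster's raw descriptors.
#'
#' @param x either the list returned by [buildDescriptorMatrix()] or a
#'   data.frame/matrix of descriptor rows (non-numeric columns are carried
#'   as metadata, not clustered).
#' @param k_range,seed,n_init see [selectKSilhouette()].
#' @param unit cluster-unit label recorded in the result.
#' @return a [SeascapeClassification].
#' @export
#' @examples
#' samples <- generateDescriptorSamples(lapply(c("AT", "SA", "PA"),
#'                                             regionPreset), 20, seed = 1)
#' cls <- classifySeascapes(samples, k_range = c(2, 4))
#' selectedK(cls)
classifySeascapes <- function(x, k_range = c(2, 8), seed = 1, n_init = 20,
                              unit = "per_day") {
  if (is.list(x) && all(c("X", "raw") %in% names(x))) {
    X <- x$X; raw <- x$raw; unit <- x$unit
  } else {
    raw <- as.data.frame(x)
    num <- vapply(raw, is.numeric, logical(1))
    X <- .zscore(as.matrix(raw[, num, drop = FALSE]))
  }
  sel <- selectKSilhouette(X, k_range, seed, n_init)
  fit <- kmeansCluster(X, sel$k, seed, n_init)
  new("SeascapeClassification", descriptors = X, raw = raw, unit = unit,
      k = as.integer(sel$k), labels = as.integer(fit$labels),
      centroids = fit$centroids, silhouette_by_k = sel$silhouette_by_k,
      summaries = summarizeClusters(fit$labels, raw))
}
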