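# Two-pass connected-component labelling of a logical matrix under
# 4-connectivity, with union-find label equivalence. 4-connectivity keeps
# vertically adjacent layers that touch only diagonally separate, the
# conservative reading of filled-isocontour regions on a grid.
.labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nextlab <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1L) labels[i - 1L, j] else 0L
      left <- if (j > 1L) labels[i, j - 1L] else 0L
      if (up == 0L && left == 0L) {
        nextlab <- nextlab + 1L
        parent[nextlab] <- nextlab
        labels[i, j] <- nextlab
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        labels[i, j] <- min(ru, rl)
        if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
      } else {
        labels[i, j] <- max(up, left)
      }
    }
  }
  if (nextlab == 0L) return(labels)
  roots <- vapply(seq_len(nextlab), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  pos <- labels > 0L
  labels[pos] <- compact[labels[pos]]
  labels
}

# Diel label per grid column from the column's mean time and position.
.columnDiel <- function(g, threshold_deg = 18) {
  pos <- pingPositions(g)
  classifyDiel(solarAltitude(pingTimes(g), pos$lat, pos$lon), threshold_deg)
}

#' Compute descriptors of one set of member cells
#'
#' Descriptors follow the standard layer metric set: minimum depth is the
#' top edge of the shallowest member bin, maximum depth the bottom edge of
#' the deepest, width their difference, length the along-track extent of the
#' member columns, and mean Sv the linear-domain mean over member cells.
#' The date is the UTC date of the majority of member columns and the diel
#' label is `day`/`night`/`transition` when uniform, else `mixed`.
#'
#' @param cells two-column integer matrix of (depth_bin, column) indices.
#' @param g the [IntegrationGrid] the cells index into.
#' @param diel optional pre-computed per-column diel labels.
#' @return one-row data.frame of descriptors.
#' @export
computeDescriptors <- function(cells, g, diel = NULL) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2)
  if (!nrow(cells)) stop("empty cell set")
  rd <- rowData(g)
  cols <- sort(unique(cells[, 2]))
  if (is.null(diel)) diel <- .columnDiel(g)
  ds <- unique(diel[cols])
  dates <- format(pingTimes(g)[cells[, 2]], "%Y-%m-%d", tz = "UTC")
  data.frame(
    min_depth_m = min(rd$depth_top_m[cells[, 1]]),
    max_depth_m = max(rd$depth_bottom_m[cells[, 1]]),
    width_m = max(rd$depth_bottom_m[cells[, 1]]) - min(rd$depth_top_m[cells[, 1]]),
    length_m = length(cols) * metadata(g)$cell_distance_nmi * NMI_M,
    mean_sv_db = .meanDb(svMatrix(g)[cells]),
    lat = mean(pingPositions(g)$lat[cols]),
    lon = mean(pingPositions(g)$lon[cols]),
    date = names(sort(table(dates), decreasing = TRUE))[1],
    diel = if (length(ds) == 1) as.character(ds) else "mixed",
    n_cells = nrow(cells))
}

#' Extract sound scattering layers from a thresholded grid
#'
#' Connected components of the threshold mask (4-connectivity) with at least
#' `min_cells` cells become layers; smaller components are discarded with a
#' logged count. Each layer's descriptors are computed with
#' [computeDescriptors()]; layers are ordered by (date, minimum depth). The
#' member-cell index sets are kept in a `cells` list-column for
#' cross-frequency matching and diagnostics.
#'
#' @param mask logical matrix from [thresholdMask()], same dimensions as `g`.
#' @param g the [IntegrationGrid].
#' @param min_cells minimum component size retained.
#' @param diel_threshold_deg solar-altitude bound for the diel labels.
#' @return data.frame of layers (possibly 0-row) with a `cells` list-column.
#' @export
extractLayers <- function(mask, g, min_cells = 5, diel_threshold_deg = 18) {
  stopifnot(all(dim(mask) == dim(g)))
  labels <- .labelComponents(mask)
  ncomp <- max(labels)
  if (ncomp == 0L) {
    out <- data.frame(layer_id = character(0), frequency_khz = numeric(0),
                      date = character(0), min_depth_m = numeric(0),
                      max_depth_m = numeric(0), width_m = numeric(0),
                      length_m = numeric(0), mean_sv_db = numeric(0),
                      diel = character(0), n_cells = integer(0))
    out$cells <- list()
    return(out)
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  comp <- labels[labels > 0L]
  sizes <- tabulate(comp, ncomp)
  keep <- which(sizes >= min_cells)
  if (length(keep) < ncomp)
    .log("discarded %d component(s) below min_cells = %d",
         ncomp - length(keep), min_cells)
  diel <- .columnDiel(g, diel_threshold_deg)
  rows <- lapply(keep, function(k) {
    cells <- idx[comp == k, , drop = FALSE]
    cbind(computeDescriptors(cells, g, diel), cells = I(list(unname(cells))))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$date, out$min_depth_m), , drop = FALSE]
  out <- cbind(layer_id = sprintf("%gkHz-%03d", frequencyKHz(g), seq_len(nrow(out))),
               frequency_khz = frequencyKHz(g), out)
  rownames(out) <- NULL
  out
}

#' Match layers across acoustic frequencies
#'
#' Layers extracted at 18 and 38 kHz from grids on a shared ping timebase
#' (column times equal within `time_tol_s`) are matched when their
#' member-cell sets, mapped to (time, depth), overlap with Jaccard index at
#' least `jaccard_min`. Matching is greedy by descending overlap and each
#' layer joins at most one pair.
#'
#' @param layers18,layers38 layer tables from [extractLayers()].
#' @param g18,g38 the corresponding [IntegrationGrid]s.
#' @param jaccard_min minimum Jaccard overlap for a match.
#' @param time_tol_s timebase agreement tolerance (seconds).
#' @return list with `pairs` (data.frame id18, id38, jaccard), and
#'   `unmatched18`/`unmatched38` layer-id vectors.
#' @export
matchFrequencies <- function(layers18, layers38, g18, g38, jaccard_min = 0.25,
                             time_tol_s = 1) {
  if (ncol(g18) != ncol(g38) ||
      max(abs(as.numeric(pingTimes(g18)) - as.numeric(pingTimes(g38)))) > time_tol_s)
    stop("grids do not share a ping timebase (column times differ by more than ",
         time_tol_s, " s)")
  key <- function(cells, g)
    paste(rowData(g)$depth_top_m[cells[, 1]], cells[, 2])
  k18 <- lapply(layers18$cells, key, g = g18)
  k38 <- lapply(layers38$cells, key, g = g38)
  cand <- expand.grid(i = seq_along(k18), j = seq_along(k38))
  cand$jaccard <- mapply(function(i, j) {
    a <- k18[[i]]; b <- k38[[j]]
    length(intersect(a, b)) / length(union(a, b))
  }, cand$i, cand$j)
  cand <- cand[cand$jaccard >= jaccard_min, , drop = FALSE]
  cand <- cand[order(-cand$jaccard), , drop = FALSE]
  used_i <- used_j <- integer(0)
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (i %in% used_i || j %in% used_j) next
    used_i <- c(used_i, i); used_j <- c(used_j, j)
    pairs[[length(pairs) + 1]] <- data.frame(
      id18 = layers18$layer_id[i], id38 = layers38$layer_id[j],
      jaccard = cand$jaccard[r])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id18 = character(0), id38 = character(0), jaccard = numeric(0))
  list(pairs = pairs,
       unmatched18 = setdiff(layers18$layer_id, pairs$id18),
       unmatched38 = setdiff(layers38$layer_id, pairs$id38))
}
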