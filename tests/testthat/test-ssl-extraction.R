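# grid whose geometry we control exactly: one ping per 0.1 nmi column
toy_grid <- function(sv) {
  n <- ncol(sv)
  eg <- Echogram(sv, depth_m = seq_len(nrow(sv)) - 0.5,
                 ping_time = as.POSIXct("2021-12-11 13:00:00", tz = "UTC") +
                   seq_len(n) * 36,
                 lat = rep(28, n), lon = -15.5 - (seq_len(n) - 1) * 0.1 / 60 /
                   cos(28 * pi / 180),
                 frequency_khz = 38)
  echoIntegrate(eg, 0.1, 1)
}

test_that("an all-false mask yields no layers", {
  g <- toy_grid(matrix(-85, 6, 4))
  out <- extractLayers(thresholdMask(g, -70), g)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("layer_id", "min_depth_m", "mean_sv_db") %in% names(out)))
})

test_that("component labelling agrees with a recursive flood fill", {
  # diagonal-touching blobs stay separate under 4-connectivity
  m <- matrix(FALSE, 5, 5)
  m[1:2, 1:2] <- TRUE
  m[3:4, 3:4] <- TRUE
  lab <- echoscape:::.labelComponents(m)
  expect_equal(max(lab), 2L)
  expect_true(same_partition(lab, oracle_flood_fill(m)))

  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(runif(12 * 15) < 0.4, 12, 15)
    expect_true(same_partition(echoscape:::.labelComponents(m),
                               oracle_flood_fill(m)))
  }
})

test_that("extracted layers partition the mask and keep only large blobs", {
  set.seed(32)
  sv <- matrix(-85, 20, 12)
  sv[3:7, 2:9] <- -65          # 40-cell layer
  sv[15, 11] <- -60            # below min_cells speckle
  g <- toy_grid(sv)
  mask <- thresholdMask(g, -70)
  out <- extractLayers(mask, g, min_cells = 5)
  expect_equal(nrow(out), 1L)
  covered <- do.call(rbind, out$cells)
  expect_equal(nrow(covered) + 1L, sum(mask))   # 1 discarded speckle cell
  expect_equal(anyDuplicated(paste(covered[, 1], covered[, 2])), 0L)
})

test_that("descriptors follow bin-edge arithmetic and linear-mean Sv", {
  sv <- matrix(-85, 450, 4)
  sv[301:400, 2:3] <- -65
  g <- toy_grid(sv)
  out <- extractLayers(thresholdMask(g, -70), g)
  expect_equal(out$min_depth_m, 300)
  expect_equal(out$max_depth_m, 400)
  expect_equal(out$width_m, 100)
  expect_equal(out$length_m, 2 * 0.1 * 1852)

  g2 <- toy_grid(matrix(c(-70, -60, -85, -85), 2, 2))
  d2 <- computeDescriptors(rbind(c(1, 1), c(2, 1)), g2)
  expect_equal(d2$mean_sv_db, -62.5963731, tolerance = 1e-6)

  single <- computeDescriptors(matrix(c(10, 1), 1), g)
  expect_equal(single$width_m, 1)
  expect_error(computeDescriptors(matrix(numeric(0), ncol = 2), g), "empty")
})

test_that("a synthetic Atlantic day scene gives one mesopelagic layer", {
  g <- make_day_grid(regionPreset("AT"), hours = 2, ping_s = 30)
  out <- extractLayers(thresholdMask(g, -70), g)
  expect_equal(nrow(out), 1L)
  expect_gte(out$min_depth_m, 300)
  expect_lte(out$max_depth_m, 700)
  expect_equal(out$diel, "day")
})

test_that("raising the threshold never grows width or linear energy", {
  g <- make_day_grid(regionPreset("PA"), hours = 1, ping_s = 60)
  prev_width <- Inf; prev_energy <- Inf
  for (thr in c(-72, -70, -68, -66)) {
    out <- extractLayers(thresholdMask(g, thr), g, min_cells = 1)
    width <- if (nrow(out)) max(out$width_m) else 0
    energy <- sum(vapply(out$cells, function(cc)
      sum(dbToLinear(svMatrix(g)[cc])), numeric(1)))
    expect_lte(width, prev_width)
    expect_lte(energy, prev_energy + 1e-15)
    prev_width <- width; prev_energy <- energy
  }
})

test_that("identical masks at both frequencies match with Jaccard 1", {
  sv <- matrix(-85, 30, 6)
  sv[5:10, 2:5] <- -65
  sv[20:24, 1:6] <- -64
  g18 <- toy_grid(sv); g38 <- toy_grid(sv)
  l18 <- extractLayers(thresholdMask(g18, -70), g18)
  l38 <- extractLayers(thresholdMask(g38, -70), g38)
  mt <- matchFrequencies(l18, l38, g18, g38)
  expect_equal(nrow(mt$pairs), 2L)
  expect_equal(mt$pairs$jaccard, c(1, 1))
  expect_length(mt$unmatched18, 0)
})

test_that("disjoint timebases are rejected", {
  sv <- matrix(-65, 4, 3)
  g18 <- toy_grid(sv)
  eg <- Echogram(sv, depth_m = 1:4 - 0.5,
                 ping_time = as.POSIXct("2021-12-11 14:00:00", tz = "UTC") +
                   (1:3) * 36, lat = rep(28, 3),
                 lon = -15.5 - (0:2) * 0.1 / 60 / cos(28 * pi / 180),
                 frequency_khz = 38)
  g38 <- echoIntegrate(eg, 0.1, 1)
  l <- extractLayers(thresholdMask(g18, -70), g18, min_cells = 1)
  expect_error(matchFrequencies(l, l, g18, g38), "timebase")
})

test_that("greedy matching equals the brute-force maximum-overlap assignment", {
  set.seed(33)
  for (rep in 1:5) {
    sv18 <- matrix(-85, 25, 8); sv38 <- matrix(-85, 25, 8)
    for (b in 1:3) {
      r <- sample(3:20, 1); cc <- sample(1:5, 1)
      sv18[r:(r + 3), cc:(cc + 2)] <- -65
      r2 <- min(25 - 3, r + sample(-2:2, 1)); c2 <- min(6, max(1, cc + sample(-1:1, 1)))
      sv38[r2:(r2 + 3), c2:(c2 + 2)] <- -64
    }
    g18 <- toy_grid(sv18); g38 <- toy_grid(sv38)
    l18 <- extractLayers(thresholdMask(g18, -70), g18, min_cells = 1)
    l38 <- extractLayers(thresholdMask(g38, -70), g38, min_cells = 1)
    if (!nrow(l18) || !nrow(l38)) next
    mt <- matchFrequencies(l18, l38, g18, g38, jaccard_min = 0.25)
    jmat <- outer(seq_len(nrow(l18)), seq_len(nrow(l38)),
                  Vectorize(function(i, j) {
                    a <- paste(l18$cells[[i]][, 1], l18$cells[[i]][, 2])
                    b <- paste(l38$cells[[j]][, 1], l38$cells[[j]][, 2])
                    length(intersect(a, b)) / length(union(a, b))
                  }))
    best <- oracle_max_overlap_pairs(jmat, 0.25)
    expect_equal(nrow(mt$pairs), length(best))
    got <- sum(mt$pairs$jaccard)
    opt <- sum(vapply(best, function(p) jmat[p[1], p[2]], numeric(1)))
    expect_equal(got, opt, tolerance = 1e-9)
  }
})
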