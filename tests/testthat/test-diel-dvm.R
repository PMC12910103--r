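test_that("solar altitude matches an independent ephemeris within 0.3 degrees", {
  # overhead sun at an equinox
  expect_lt(abs(solarAltitude(as.POSIXct("2021-03-20 12:07:00", tz = "UTC"),
                              0, 0) - 90), 0.5)
  # survey-era spot checks across the tropics
  set.seed(41)
  t10 <- as.POSIXct("2021-12-11 00:00:00", tz = "UTC") +
    runif(10, 0, 32 * 86400)
  lat10 <- runif(10, -10, 30)
  lon10 <- runif(10, -90, -15)
  expect_lt(max(abs(solarAltitude(t10, lat10, lon10) -
                      oracle_solar_altitude(t10, lat10, lon10))), 0.3)
  expect_lt(abs(solarAltitude(as.POSIXct("2021-12-11 13:00:00", tz = "UTC"),
                              28, -15.5) -
                  oracle_solar_altitude(as.POSIXct("2021-12-11 13:00:00",
                                                   tz = "UTC"), 28, -15.5)),
            0.3)
})

test_that("solar altitude is 24 h-periodic to within a degree per day", {
  t0 <- as.POSIXct("2021-12-20 06:00:00", tz = "UTC") + seq(0, 86399, 3600)
  a0 <- solarAltitude(t0, 15, -45)
  a1 <- solarAltitude(t0 + 86400, 15, -45)
  expect_lt(max(abs(a1 - a0)), 1)
})

test_that("diel classification follows the +-18 degree convention", {
  expect_equal(classifyDiel(30), "day")
  expect_equal(classifyDiel(-30), "night")
  expect_equal(classifyDiel(18), "transition")
  expect_equal(classifyDiel(-18), "transition")
  expect_equal(classifyDiel(18 + 1e-9), "day")
  expect_equal(classifyDiel(c(45, 0, -45)), c("day", "transition", "night"))
})

test_that("a simulated tropical day partitions into all three diel phases", {
  t24 <- as.POSIXct("2021-12-15 00:00:00", tz = "UTC") + seq(0, 86399, 120)
  phases <- classifyDiel(solarAltitude(t24, 7, -85))
  counts <- table(factor(phases, c("day", "night", "transition")))
  expect_true(all(counts > 0))
  expect_equal(sum(counts), length(t24))
  expect_gt(counts[["transition"]], 0)
})

test_that("day/night mean profiles and their difference behave", {
  # single-bin toy: night column -60 dB, day column -70 dB -> delta +10 dB
  eg <- Echogram(matrix(c(-60, -70), 1, 2), depth_m = 100.5,
                 ping_time = as.POSIXct(c("2021-12-15 02:00:00",
                                          "2021-12-15 13:00:00"), tz = "UTC"),
                 lat = c(7, 7), lon = c(-85, -85.01), frequency_khz = 38)
  g <- echoIntegrate(eg, 0.001, 1)
  prof <- meanProfiles(g, diel = c("night", "day"))
  expect_equal(prof$delta_db, 10)
  expect_equal(prof$mean_sv_day, -70)
  expect_equal(prof$mean_sv_night, -60)

  # identical day and night fields give zero delta everywhere
  g2 <- make_day_grid(regionPreset("SA"), hours = 0.5, ping_s = 60)
  half <- rep(c("day", "night"), length.out = ncol(g2))
  same <- meanProfiles(g2, diel = half)
  # columns are near-identical up to jitter; delta is near zero
  expect_lt(max(abs(same$delta_db), na.rm = TRUE), 1)
  expect_error(meanProfiles(g2, diel = rep("day", ncol(g2))), "night")
})

test_that("migrating layers produce the canonical delta sign pattern", {
  pre <- regionPreset("AT", layers = list(layerSpec(430, 80, sigma_depth = 35,
                                                    peak_sv = -65)))
  eg <- generateEchogram(pre, 38, as.POSIXct("2021-12-15 00:00:00", tz = "UTC"),
                         duration_hours = 24, ping_interval_s = 180,
                         depth_max = 800, seed = 8)
  g <- echoIntegrate(applySurfaceOffset(eg, 10))
  prof <- meanProfiles(g)
  shallow <- prof$depth_m > 50 & prof$depth_m < 120   # night band core
  deep <- prof$depth_m > 390 & prof$depth_m < 470     # day band core
  expect_true(all(prof$delta_db[shallow] > 0))
  expect_true(all(prof$delta_db[deep] < 0))
})

test_that("WMD equals the direct weighted sum and sits between extremes", {
  # symmetric Gaussian layer centred at 400 m
  z <- seq(0.5, 799.5)
  sv <- linearToDb(1e-9 + 1e-6 * exp(-(z - 400)^2 / (2 * 30^2)))
  expect_lt(abs(computeWMD(sv, z) - 400), 1)
  # two equal linear intensities
  expect_equal(computeWMD(c(-60, -60), c(100, 300)), 200)
  # random column vs direct sum
  set.seed(43)
  for (rep in 1:5) {
    svr <- runif(50, -90, -55)
    svr[sample(50, 5)] <- NA
    zr <- seq_len(50) * 2
    keep <- !is.na(svr)
    direct <- sum(zr[keep] * 10^(svr[keep] / 10)) / sum(10^(svr[keep] / 10))
    expect_equal(computeWMD(svr, zr), direct)
    expect_gte(computeWMD(svr, zr), min(zr[keep]))
    expect_lte(computeWMD(svr, zr), max(zr[keep]))
    # invariance under a constant dB shift
    expect_equal(computeWMD(svr + 7.3, zr), computeWMD(svr, zr),
                 tolerance = 1e-9)
  }
  expect_true(is.na(computeWMD(rep(NA_real_, 3), 1:3)))
})

test_that("cross-frequency validation reports r and diel amplitudes", {
  w <- function(v) data.frame(time = seq_along(v), lat = 0, lon = 0, wmd_m = v)
  diel <- rep(c("day", "night"), each = 3)
  ident <- crossFrequencyValidation(w(c(400, 410, 390, 80, 90, 100)),
                                    w(c(400, 410, 390, 80, 90, 100)), diel)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$amplitude_day_night_18, 90 - 400)
  mirror <- crossFrequencyValidation(w(1:6), w(6:1), rep("day", 6))
  expect_equal(mirror$pearson_r, -1)
  # random pair vs the covariance formula
  set.seed(44)
  a <- runif(20, 100, 500); b <- a + rnorm(20, 0, 40)
  got <- crossFrequencyValidation(w(a), w(b), rep(c("day", "night"), 10))
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$pearson_r, direct)
  expect_error(crossFrequencyValidation(w(1:2), w(1:2), c("day", "night")),
               "at least 3")
  expect_warning(crossFrequencyValidation(w(rep(1, 5)), w(1:5), rep("day", 5)),
                 "zero variance")
})
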