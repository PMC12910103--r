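presets3 <- lapply(c("AT", "SA", "PA"), regionPreset)

test_that("generation is deterministic given (preset, seed)", {
  a <- generateEchogram(regionPreset("SA"), 38,
                        as.POSIXct("2021-12-20 00:00:00", tz = "UTC"),
                        duration_hours = 1, ping_interval_s = 60,
                        depth_max = 800, seed = 9)
  b <- generateEchogram(regionPreset("SA"), 38,
                        as.POSIXct("2021-12-20 00:00:00", tz = "UTC"),
                        duration_hours = 1, ping_interval_s = 60,
                        depth_max = 800, seed = 9)
  expect_identical(svMatrix(a), svMatrix(b))
  s1 <- generateCTD(regionPreset("AT"), 2, seed = 5)
  s2 <- generateCTD(regionPreset("AT"), 2, seed = 5)
  expect_identical(ctdProfile(s1[[2]]), ctdProfile(s2[[2]]))
  d1 <- generateDescriptorSamples(presets3, 5, seed = 3)
  d2 <- generateDescriptorSamples(presets3, 5, seed = 3)
  expect_identical(d1, d2)
})

test_that("the Atlantic daytime layer core sits in the mesopelagic stratum", {
  eg <- generateEchogram(regionPreset("AT"), 38,
                         as.POSIXct("2021-12-15 13:00:00", tz = "UTC"),
                         duration_hours = 1, ping_interval_s = 60,
                         depth_max = 800, seed = 1)
  sv <- svMatrix(eg)
  core <- depthAxis(eg)[apply(sv, 2, which.max)]
  expect_true(all(core >= 300 & core <= 700))
})

test_that("an empty layer list over a -90 dB floor never crosses -70 dB", {
  pre <- regionPreset("AT", layers = list(), noise_floor_sv = -90)
  eg <- generateEchogram(pre, 38, as.POSIXct("2021-12-15 12:00:00", tz = "UTC"),
                         duration_hours = 1, ping_interval_s = 60,
                         depth_max = 800, seed = 2)
  expect_true(all(svMatrix(eg) < -70))
})

test_that("dB jitter preserves the configured linear-mean peak level", {
  pre <- regionPreset("AT",
                      layers = list(layerSpec(400, 400, sigma_depth = 30,
                                              peak_sv = -63, sv_jitter_sd = 1,
                                              persistent = TRUE)),
                      noise_floor_sv = -110)
  eg <- generateEchogram(pre, 38, as.POSIXct("2021-12-15 00:00:00", tz = "UTC"),
                         duration_hours = 10, ping_interval_s = 36,
                         depth_max = 800, seed = 6)
  core <- svMatrix(eg)[match(400.5, depthAxis(eg)), ]
  expect_gt(length(core), 999)
  expect_lt(abs(linearToDb(mean(dbToLinear(core))) - (-63)), 0.5)
})

test_that("a too-shallow grid for the configured layers is rejected", {
  expect_error(generateEchogram(regionPreset("AT"), 38,
                                as.POSIXct("2021-12-15 12:00:00", tz = "UTC"),
                                1, depth_max = 200, seed = 1),
               "shallower than the deepest")
})

test_that("CTD regimes reproduce the regional hydrography", {
  # thermocline = depth of max |dT/dz|, estimated between profile samples
  grad_depth <- function(p) {
    i <- which.max(abs(diff(p$temperature) / diff(p$depth_m)))
    (p$depth_m[i] + p$depth_m[i + 1]) / 2
  }
  sa <- ctdProfile(generateCTD(regionPreset("SA"), 1, seed = 1,
                               noise_scale = 0)[[1]])
  expect_lte(abs(grad_depth(sa) - 300), 20)

  pa <- ctdProfile(generateCTD(regionPreset("PA"), 1, seed = 1)[[1]])
  expect_lte(min(pa$oxygen[pa$depth_m > 200]), 25)
  expect_lt(pa$salinity[1], 33)

  at <- ctdProfile(generateCTD(regionPreset("AT"), 1, seed = 1,
                               noise_scale = 0)[[1]])
  expect_lte(abs(grad_depth(at) - 100), 20)
})

test_that("zero-noise CTD profiles equal their analytic forms exactly", {
  pre <- regionPreset("PA")
  st <- generateCTD(pre, 1, seed = 7, noise_scale = 0)[[1]]
  p <- ctdProfile(st)
  expect_equal(p, ctdAnalyticProfile(pre, p$depth_m))
  expect_error(generateCTD(regionPreset("PA",
                             ctd_params = list(omz_min_oxygen = -5)), 1),
               "omz_min_oxygen")
})

test_that("descriptor samples follow the regional regimes", {
  d <- generateDescriptorSamples(presets3, 400, seed = 2)
  pa <- d[d$region == "PA", ]
  sa <- d[d$region == "SA", ]
  at <- d[d$region == "AT", ]
  expect_lt(abs(mean(pa$min_depth_18) - 10), 2)
  expect_lt(abs(mean((sa$mean_sv_18 + sa$mean_sv_38) / 2) - (-67)), 0.5)
  expect_lt(abs(mean(at$max_depth_18) - 400), 5)
  expect_lt(abs(mean(pa$width_18) - 150), 3)
  expect_lt(abs(mean(pa$width_38) - 120), 3)

  d0 <- generateDescriptorSamples(presets3, 3, seed = 2, spread = 0)
  expect_equal(unname(vapply(split(d0$width_18, d0$region), stats::sd,
                             numeric(1))), c(0, 0, 0))
  expect_error(generateDescriptorSamples(presets3, 1), "n_per_region")
  expect_error(generateDescriptorSamples(presets3[1], 10), "two region")
})

test_that("night-minus-day WMD matches the configured migration distance", {
  pre <- regionPreset("AT", layers = list(layerSpec(430, 80, sigma_depth = 35,
                                                    peak_sv = -65)))
  eg <- generateEchogram(pre, 38, as.POSIXct("2021-12-15 00:00:00", tz = "UTC"),
                         duration_hours = 24, ping_interval_s = 120,
                         depth_max = 800, seed = 3)
  g <- echoIntegrate(applySurfaceOffset(eg, 10))
  pos <- pingPositions(g)
  diel <- classifyDiel(solarAltitude(pingTimes(g), pos$lat, pos$lon))
  w <- wmdSeries(g, threshold_db = -70)$wmd_m
  amp <- mean(w[diel == "night"], na.rm = TRUE) -
    mean(w[diel == "day"], na.rm = TRUE)
  expect_lt(abs(amp - (80 - 430)), 5)
})
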