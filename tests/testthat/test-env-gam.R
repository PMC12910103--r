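# simulated matched records with controllable response surface
sim_records <- function(n, seed = 1, response_fun = NULL, sigma = 0.1) {
  set.seed(seed)
  rec <- data.frame(
    temperature = rnorm(n), salinity = rnorm(n), oxygen = runif(n, -1, 1),
    chlorophyll_a = rnorm(n), par = rnorm(n),
    location = sample(c("AT", "SA", "PA"), n, replace = TRUE),
    diel = sample(c("day", "night"), n, replace = TRUE))
  mu <- if (is.null(response_fun)) 0 else response_fun(rec)
  rec$sv18 <- mu + rnorm(n, 0, sigma)
  rec$sv38 <- mu + rnorm(n, 0, sigma)
  rec
}

test_that("haversine distance agrees with the spherical law of cosines", {
  set.seed(61)
  lat1 <- runif(50, -60, 60); lon1 <- runif(50, -180, 180)
  lat2 <- lat1 + rnorm(50, 0, 0.5); lon2 <- lon1 + rnorm(50, 0, 0.5)
  d1 <- haversineNmi(lat1, lon1, lat2, lon2)
  d2 <- oracle_dist_nmi(lat1, lon1, lat2, lon2)
  expect_lt(max(abs(d1 - d2)) * 1852, 1)   # within 1 m at these scales
  expect_equal(haversineNmi(0, 0, 0, 1 / 60), 1.00028, tolerance = 1e-3)
})

test_that("stations match acoustic columns only within the radius", {
  g <- make_day_grid(regionPreset("AT"), hours = 1, ping_s = 60)
  pos <- pingPositions(g)
  prof <- ctdAnalyticProfile(regionPreset("AT"), seq(5, 800, 5))
  on_track <- CTDStation("AT-99", pos$lat[5], pos$lon[5],
                         pingTimes(g)[5], prof)
  rec <- matchAcousticToCtd(g, g, list(on_track))
  expect_gte(nrow(rec), 1)
  expect_equal(unique(rec$location), "AT")
  expect_true(all(rec$sv18 >= -70))

  far <- CTDStation("AT-98", pos$lat[5] + 0.2 / 60, pos$lon[5],
                    pingTimes(g)[5], prof)   # 0.2 nmi north of the track
  expect_error(matchAcousticToCtd(g, g, list(far)), "no CTD station matched")
})

test_that("matched predictors are profile means over the layer stratum", {
  g <- make_day_grid(regionPreset("AT"), hours = 0.5, ping_s = 60)
  pos <- pingPositions(g)
  prof <- ctdAnalyticProfile(regionPreset("AT"), seq(5, 800, 5))
  st <- CTDStation("AT-01", pos$lat[2], pos$lon[2], pingTimes(g)[2], prof)
  rec <- matchAcousticToCtd(g, g, list(st))
  zi <- seq(rec$depth_top_m[1] + 0.5, rec$depth_bottom_m[1] - 0.5)
  direct <- mean(approx(prof$depth_m, prof$oxygen, zi, rule = 2)$y)
  expect_equal(rec$oxygen[1], direct)
})

test_that("collinearity screening flags duplicates and excludes turbidity", {
  rec <- sim_records(1000, seed = 3)
  rec$turbidity <- rec$chlorophyll_a          # perfectly collinear proxy
  scr <- screenCollinearity(rec)
  hit <- scr$flags$var1 == "turbidity" | scr$flags$var2 == "turbidity"
  expect_true(any(hit))
  expect_gt(min(scr$flags$r[hit]), 0.999)
  expect_equal(scr$excluded, "turbidity")
  # independent simulated columns stay unflagged
  indep <- screenCollinearity(sim_records(1000, seed = 4))
  off <- indep$correlations[upper.tri(indep$correlations)]
  expect_lt(max(abs(off)), 0.1)
  expect_equal(nrow(indep$flags), 0L)
  rec$const <- 1
  expect_error(screenCollinearity(rec[1:2, ]), "at least 3")
})

test_that("the two response formulas carry the expected term structure", {
  rec <- sim_records(200, seed = 5)
  f18 <- fitGam(rec, "sv18")
  t18 <- termTable(f18)
  expect_setequal(t18$term[t18$type == "smooth"],
                  c("s(chlorophyll_a)", "s(oxygen)", "s(par)"))
  expect_true(all(c("temperature", "salinity") %in%
                    t18$term[t18$type == "linear"]))
  expect_true(any(grepl("location", t18$term)))
  f38 <- fitGam(rec, "sv38")
  t38 <- termTable(f38)
  expect_setequal(t38$term[t38$type == "smooth"],
                  c("s(chlorophyll_a)", "s(oxygen)"))
  expect_true("par" %in% t38$term[t38$type == "linear"])
  expect_true(validObject(f18))
})

test_that("a pure-noise response explains almost no deviance", {
  rec <- sim_records(500, seed = 6, sigma = 1)
  fit <- fitGam(rec, "sv18")
  expect_lt(devianceExplained(fit), 5)
})

test_that("a known linear + sinusoidal surface is recovered", {
  fun <- function(d) 2 * d$temperature + sin(pi * d$oxygen)
  rec <- sim_records(500, seed = 7, response_fun = fun, sigma = 0.1)
  fit <- fitGam(rec, "sv18", standardize = FALSE)
  tt <- termTable(fit)
  expect_lt(abs(tt$estimate[tt$term == "temperature"] - 2), 0.1)
  sm <- predict(fit@model, type = "terms")[, "s(oxygen)"]
  truth <- sin(pi * rec$oxygen)
  truth <- truth - mean(truth)    # smooths are centred
  expect_lt(sqrt(mean((sm - truth)^2)), 0.15)
  expect_gt(devianceExplained(fit), 95)
})

test_that("deviance explained is monotone in nested term sets", {
  fun <- function(d) 1.5 * d$temperature + 0.8 * d$salinity + sin(pi * d$oxygen)
  rec <- sim_records(400, seed = 8, response_fun = fun, sigma = 0.3)
  full <- fitGam(rec, "sv18", fixed_smooths = TRUE)
  drop1 <- fitGam(rec, "sv18", drop_terms = "par", fixed_smooths = TRUE)
  drop2 <- fitGam(rec, "sv18", drop_terms = c("par", "salinity"),
                  fixed_smooths = TRUE)
  expect_gte(devianceExplained(full) + 1e-9, devianceExplained(drop1))
  expect_gte(devianceExplained(drop1) + 1e-9, devianceExplained(drop2))
  expect_error(fitGam(transform(rec, temperature = 1), "sv18"),
               "rank deficiency")
})

test_that("refits are bit-identical and diagnostics catch violations", {
  rec <- sim_records(300, seed = 9, sigma = 0.5)
  a <- fitGam(rec, "sv38"); b <- fitGam(rec, "sv38")
  expect_identical(devianceExplained(a), devianceExplained(b))
  expect_identical(a@aic, b@aic)
  expect_identical(termTable(a), termTable(b))

  dg <- gamDiagnostics(a)
  expect_true(dg$normality$pass)        # gaussian noise by construction
  # variance proportional to fitted values is flagged
  set.seed(10)
  fun <- function(d) 3 * d$temperature
  rec2 <- sim_records(400, seed = 10, response_fun = fun, sigma = 1e-6)
  rec2$sv18 <- 3 * rec2$temperature +
    rnorm(400, 0, 0.05 + 0.5 * abs(rec2$temperature))
  het <- gamDiagnostics(fitGam(rec2, "sv18"))
  expect_false(het$heteroscedasticity$pass)

  rec3 <- sim_records(50, seed = 11, sigma = 0)
  rec3$sv18 <- 0
  expect_warning(gamDiagnostics(fitGam(rec3, "sv18", drop_terms =
    c("chlorophyll_a", "oxygen", "par", "salinity", "temperature", "location"))),
    "degenerate|zero")
})

test_that("gaussian residuals pass the normality screen reliably", {
  passes <- vapply(1:40, function(s) {
    rec <- sim_records(150, seed = 100 + s, sigma = 0.5)
    gamDiagnostics(fitGam(rec, "sv18"))$normality$p_value > 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})
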