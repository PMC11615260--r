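mkFixes <- function(mins, animal = "A1", x = NULL, y = NULL,
                    start = as.POSIXct("2023-01-05 08:00:00", tz = "UTC")) {
  n <- length(mins)
  data.frame(animal_id = animal, timestamp = start + mins * 60,
             x = if (is.null(x)) seq(0, by = 50, length.out = n) else x,
             y = if (is.null(y)) rep(0, n) else y,
             species = "BCH")
}

test_that("greedy resampling keeps fixes at the target rate", {
  # 5-min fixes over an hour -> 0, 30, 60 survive at rate 30 +/- 5
  f <- mkFixes(seq(0, 60, by = 5))
  r <- resampleTrack(f, 30, 5)
  expect_equal(as.numeric(difftime(r$timestamp, f$timestamp[1],
                                   units = "mins")), c(0, 30, 60))
  expect_equal(unique(r$burst), 1L)

  # 45-min spacing: no admissible gap, singleton bursts all dropped
  expect_equal(nrow(resampleTrack(mkFixes(seq(0, 180, by = 45)), 30, 5)), 0)

  # already at the target rate: identity
  f30 <- mkFixes(seq(0, 120, by = 30))
  r30 <- resampleTrack(f30, 30, 5)
  expect_equal(r30$timestamp, f30$timestamp)
})

test_that("within-burst gaps always land inside the tolerance window", {
  set.seed(11)
  mins <- sort(sample(0:600, 90))
  r <- resampleTrack(mkFixes(mins), 30, 5)
  if (nrow(r) > 1) {
    gaps <- unlist(tapply(as.numeric(r$timestamp) / 60, r$burst, diff))
    expect_true(all(gaps >= 25 & gaps <= 35))
  }
  sizes <- table(r$burst)
  expect_true(all(sizes >= 3))
})

test_that("eligibility filter applies the in-area fix-count threshold", {
  poly <- cbind(c(-1, 1001, 1001, -1), c(-1, -1, 1001, 1001))
  a <- data.frame(animal_id = rep(c("A", "B"), c(999, 1000)),
                  timestamp = Sys.time() + 1:1999,
                  x = runif(1999, 0, 1000), y = runif(1999, 0, 1000),
                  species = "BCH")
  out <- filterEligible(a, minFixes = 1000, polygon = poly)
  expect_setequal(unique(out$animal_id), "B")   # 999 < 1000 excluded
  expect_equal(unname(attr(out, "counts")["A"]), 999)

  expect_warning(out2 <- filterEligible(a, 1000, poly[1:2, ]),
                 "degenerate")
  expect_equal(nrow(out2), 0)
})

test_that("steps carry lengths, wrapped turn angles and burst structure", {
  f <- mkFixes(seq(0, 120, by = 30),
               x = c(0, 100, 100, 0, 0), y = c(0, 0, 100, 100, 200))
  f$burst <- 1L
  st <- trackSteps(f)
  expect_equal(st$sl, c(100, 100, 100, 100))
  expect_true(all(st$ta > -pi & st$ta <= pi, na.rm = TRUE))
  expect_true(is.na(st$ta[1]))
  expect_equal(st$ta[-1], c(pi / 2, pi / 2, -pi / 2), tolerance = 1e-12)
})

test_that("steps spanning the nightly off window are excluded", {
  # 18:10 local start (17:10 UTC) crossing 18:30 local
  f <- mkFixes(c(0, 30, 60),
               start = as.POSIXct("2023-01-05 17:10:00", tz = "UTC"))
  f$burst <- 1L
  st <- trackSteps(f)   # first step ends 18:40 local -> crosses 18:30
  expect_equal(nrow(st), 0)

  fDay <- mkFixes(c(0, 30, 60),
                  start = as.POSIXct("2023-01-05 09:00:00", tz = "UTC"))
  fDay$burst <- 1L
  expect_equal(nrow(trackSteps(fDay)), 2)
})

test_that("temperature matching is nearest-in-time, earlier wins ties", {
  steps <- data.frame(t_end = as.POSIXct("2023-01-05 12:00:00", tz = "UTC"))
  series <- data.frame(
    timestamp = as.POSIXct(c("2023-01-05 11:45:00", "2023-01-05 12:15:00"),
                           tz = "UTC"),
    temp_c = c(21, 28))
  expect_equal(attachTemperature(steps, series)$temperature, 21)

  # nearest record beyond the window -> missing
  far <- data.frame(timestamp = steps$t_end - 90 * 60, temp_c = 19)
  expect_true(is.na(attachTemperature(steps, far, maxGap = 60)$temperature))

  exact <- data.frame(timestamp = steps$t_end, temp_c = 25)
  expect_equal(attachTemperature(steps, exact)$temperature, 25)
})

test_that("strata have one used + K controls sharing origin and time", {
  stack <- makeStack(200)    # 2 km; short steps keep controls on-raster
  tk <- defaultTentative(slShape = 2, slRate = 0.05)
  set.seed(3)
  f <- mkFixes(seq(0, 300, by = 30),
               x = runif(11, 900, 1100), y = runif(11, 900, 1100))
  f$burst <- 1L
  st <- trackSteps(f)
  strata <- buildStrata(st, stack, tk, kControls = 10, seed = 9)
  sizes <- table(strata$stratum_id)
  expect_true(all(sizes == 11))                       # 1 used + 10 controls
  expect_equal(as.vector(tapply(strata$case, strata$stratum_id, sum)),
               rep(1L, length(sizes)))
  for (sid in unique(strata$stratum_id)) {
    g <- strata[strata$stratum_id == sid, ]
    expect_equal(diff(range(g$x_start)), 0)
    expect_equal(diff(range(g$y_start)), 0)
    expect_length(unique(g$t_start), 1)
  }
  # determinism under a fixed seed
  strata2 <- buildStrata(st, stack, tk, 10, seed = 9)
  expect_identical(strata, strata2)
  expect_error(buildStrata(st, stack, tk, 0), ">= 1")
})

test_that("strata touching nodata or the raster edge are dropped", {
  v <- matrix(30, 40, 40); v[, 21:40] <- NA    # right half nodata
  stack <- makeStack(40, canopy = v)
  f <- mkFixes(seq(0, 300, by = 30), x = rep(c(195, 205), 6)[1:11],
               y = rep(200, 11))
  f$burst <- 1L
  st <- trackSteps(f)
  strata <- buildStrata(st, stack, defaultTentative(), 10, seed = 1)
  expect_gt(attr(strata, "dropped"), 0)
  if (nrow(strata))
    expect_true(all(!is.na(strata$canopy_height)))
})

test_that("standardization is per animal with sample sd", {
  d <- data.frame(animal_id = rep(c("A", "B"), each = 2),
                  stratum_id = 1:4, case = 1L,
                  canopy_height = c(0, 10, 5, 15), swamp = c(0, 1, 0, 1))
  out <- standardizeCovariates(d, vars = "canopy_height")
  z <- out$data$canopy_height
  expect_equal(z, c(-1, 1, -1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$standardization$sd, c(sd(c(0, 10)), sd(c(5, 15))))
  expect_equal(out$data$swamp, d$swamp)    # binary untouched

  # idempotence up to tolerance and per-animal moments
  twice <- standardizeCovariates(out$data, vars = "canopy_height")
  expect_equal(twice$data$canopy_height, z, tolerance = 1e-9)
  for (a in c("A", "B")) {
    za <- out$data$canopy_height[out$data$animal_id == a]
    expect_equal(mean(za), 0, tolerance = 1e-9)
    expect_equal(sd(za), 1, tolerance = 1e-9)
  }
  dBad <- d; dBad$canopy_height <- 1
  expect_error(standardizeCovariates(dBad, vars = "canopy_height"),
               "canopy_height")
})

test_that("movebank-style CSV reading handles lon/lat and duplicates", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    `individual-local-identifier` = c("h1", "h1", "h1"),
    timestamp = c("2023-01-05 08:00:00", "2023-01-05 08:00:00",
                  "2023-01-05 08:05:00"),
    `location-long` = c(12.80, 12.80, 12.81),
    `location-lat` = c(3.18, 3.18, 3.19), check.names = FALSE)
  write.csv(df, p, row.names = FALSE)
  fx <- readFixes(p, species = "BCH")
  expect_equal(nrow(fx), 2)    # exact duplicate dropped
  # ~0.01 deg lat = ~1.11 km
  expect_equal(diff(fx$y), 0.01 * pi / 180 * 6371008.8, tolerance = 1e-6)
})
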