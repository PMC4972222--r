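## build a 2-h series from a vector of daily mean levels (12 readings/day)
seriesFromDaily <- function(levels, startDoy = 1, jitter = 0, seed = 1) {
  nd <- length(levels)
  doy <- rep(startDoy + seq_len(nd) - 1L, each = 12L)
  set.seed(seed)
  temp <- rep(levels, each = 12L) + rnorm(12L * nd, 0, jitter)
  data.frame(doy = doy, hour = rep(seq(0, 22, 2), nd), temp_c = temp)
}

test_that("snowmelt day is the first rise after a sustained near-zero flat period", {
  ## 10 flat days then a step to 6 degC on day 11
  s <- seriesFromDaily(c(rep(0, 10), rep(6, 5)), jitter = 0.2, seed = 2)
  expect_equal(detectSnowmeltDay(s), 11L)
  ## a series that never sat near zero has no snow-cover signature
  s2 <- seriesFromDaily(rep(8, 20))
  expect_error(detectSnowmeltDay(s2), "no snow-cover signature")
  ## ramp crossing 1.5 degC on day 14 after 8 flat days
  ramp <- c(rep(0, 8), 0.7, 0.9, 1.1, 1.3, 1.45, 1.6, 2, 3)
  s3 <- seriesFromDaily(ramp)
  expect_equal(detectSnowmeltDay(s3), 14L)
  ## invariant to a 2-h phase shift of the sampling grid
  s3shift <- s3
  s3shift$hour <- (s3shift$hour + 2) %% 24
  expect_equal(detectSnowmeltDay(s3shift), 14L)
  ## flat period exists but no rise afterwards
  s4 <- seriesFromDaily(rep(0, 10))
  expect_error(detectSnowmeltDay(s4), "rise")
})

test_that("snowmelt detection tolerates sub-threshold noise and multiple loggers", {
  hits <- vapply(1:30, function(s) {
    ser <- seriesFromDaily(c(rep(0, 12), rep(5, 6)), jitter = 0.1, seed = s)
    detectSnowmeltDay(ser) == 13L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  ## per-logger detection with the site value as the median
  multi <- do.call(rbind, lapply(1:5, function(lg) {
    melt <- c(12, 12, 13, 13, 14)[lg]
    ser <- seriesFromDaily(c(rep(0, melt - 1), rep(6, 8)), seed = lg)
    ser$logger <- lg
    ser
  }))
  expect_equal(detectSnowmeltDay(multi), 13L)
})

test_that("growing-degree days match hand sums and are window-additive", {
  s <- seriesFromDaily(rep(10, 5))
  expect_equal(as.numeric(gdd(s, 1, 5)), 25)
  sLow <- seriesFromDaily(rep(3, 5))
  expect_equal(as.numeric(gdd(sLow, 1, 5)), 0)
  sMix <- seriesFromDaily(c(7, 6, 4, 10))
  expect_equal(as.numeric(gdd(sMix, 1, 4)), 8)
  ## additive over contiguous windows on a random series
  set.seed(6)
  sR <- seriesFromDaily(runif(20, 0, 12), jitter = 0.3, seed = 7)
  expect_equal(as.numeric(gdd(sR, 1, 8)) + as.numeric(gdd(sR, 9, 20)),
               as.numeric(gdd(sR, 1, 20)), tolerance = 1e-10)
  ## days with too many missing readings are excluded and reported
  sHole <- seriesFromDaily(rep(10, 5))
  sHole <- sHole[!(sHole$doy == 3 & sHole$hour < 10), ]  # 5 of 12 readings lost
  expect_message(g <- gdd(sHole, 1, 5), "excluding 1 day")
  expect_equal(as.numeric(g), 20)
  expect_equal(attr(g, "excludedDays"), 3)
  expect_error(gdd(s, 5, 1), "startDay")
})

test_that("leaf area is the ellipse formula", {
  expect_equal(leafArea(4, 2), 2 * pi)
  expect_equal(leafArea(0, 5), 0)
  expect_equal(mean(leafArea(c(4, 6), c(2, 4))), 12.56637, tolerance = 1e-6)
  expect_error(leafArea(-1, 2), "non-negative")
})

test_that("standardization matches hand moments and keeps missing values", {
  expect_equal(standardizeTraits(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8); x <- rnorm(50, 5, 2)
  z <- standardizeTraits(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  xm <- c(2, 4, NA, 6, 8)
  zm <- standardizeTraits(xm)
  expect_equal(zm, (xm - 5) / sd(c(2, 4, 6, 8)))
  expect_true(is.na(zm[3]))
  expect_error(standardizeTraits(rep(3, 4)), "constant")
})

test_that("derived traits match an independent spreadsheet-style recomputation", {
  tempA <- simulateTemperature(160, site = "A", noiseSD = 0, winterSD = 0,
                               seed = 1)
  tempB <- simulateTemperature(175, site = "B", noiseSD = 0, winterSD = 0,
                               seed = 2)
  rec <- data.frame(
    patch = paste0("p", 1:6),
    site = c("A", "A", "A", "B", "B", "B"),
    microhabitat = c("ridge", "ridge", "ridge", "snowbed", "snowbed", "snowbed"),
    elevation = "low", transect = "T1",
    leaf_expansion_day = c(174, 170, NA, 185, 150, 190),
    flowering_day = c(190, 180, 188, 200, 195, 205),
    stems_2011 = c(10, 8, 5, 0, 4, 6),
    stems_2012 = c(15, 8, 0, 5, 6, 9),
    flowering_stems_2012 = c(3, 4, 0, 2, 3, 9),
    leaf_length = c(4, 6, 5, 4, 5, NA), leaf_width = c(2, 4, 3, 3, 2, 3))
  out <- deriveTraits(rec, temperature = rbind(tempA, tempB))
  expect_equal(out$snowmelt_day, c(160, 160, 160, 175, 175, 175))
  expect_equal(out$snowmelt_to_leaf_expansion[1], 14)
  expect_equal(out$change_in_stem_number[1], 1.5)
  ## ratio undefined when stems_2011 = 0; proportion undefined when 2012 = 0
  expect_true(is.na(out$change_in_stem_number[4]))
  expect_true(is.na(out$proportion_flowering_stems[3]))
  expect_equal(out$proportion_flowering_stems[6], 1)
  ## phenophase before snowmelt is flagged, not used
  expect_true(out$flag_negative_interval[5])
  expect_true(is.na(out$snowmelt_to_leaf_expansion[5]))
  ## leaf size, NA propagation
  expect_equal(out$leaf_size[1], leafArea(4, 2))
  expect_true(is.na(out$leaf_size[6]))
  ## independent GDD recomputation from daily means of the raw series
  manualGdd <- function(series, from, to) {
    dm <- tapply(series$temp_c, series$doy, mean)
    doy <- as.numeric(names(dm))
    sum(pmax(dm[doy >= from & doy <= to] - 5, 0))
  }
  expect_equal(out$gdd_to_leaf_expansion[1], manualGdd(tempA, 160, 174),
               tolerance = 1e-10)
  expect_equal(out$gdd_to_flowering[4], manualGdd(tempB, 175, 200),
               tolerance = 1e-10)
  ## interval traits missing when the phenophase is unobserved
  expect_true(is.na(out$snowmelt_to_leaf_expansion[3]))
  expect_true(is.na(out$gdd_to_leaf_expansion[3]))
})
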