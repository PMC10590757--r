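test_that("calibration fitting solves the normal equations", {
  exact <- data.frame(ratio = c(0.5, 1, 1.5, 2), ph = 4 + 2 * c(0.5, 1, 1.5, 2))
  fit <- fitCalibration(exact)
  expect_equal(fit@intercept, 4, tolerance = 1e-12)
  expect_equal(fit@slope, 2, tolerance = 1e-12)
  expect_equal(fit@phRange, c(5, 8))
  expect_lt(fit@residualSd, 1e-12)

  ## hand least squares on (R, pH) = (1,5), (2,6), (3,7.3): b = 1.15,
  ## a = 3.8; a fourth point placed on that line leaves the fit unchanged
  hand <- data.frame(ratio = c(1, 2, 3, 4), ph = c(5, 6, 7.3, 3.8 + 1.15 * 4))
  fit2 <- fitCalibration(hand)
  expect_equal(fit2@slope, 1.15, tolerance = 1e-12)
  expect_equal(fit2@intercept, 3.8, tolerance = 1e-12)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fitCalibration(data.frame(ratio = 1:3, ph = c(5, 6, 7))),
               "at least 4")
  expect_error(fitCalibration(data.frame(ratio = 1:4, ph = c(6, 6.2, 6.4, 6.6))),
               "1.5 pH")
  expect_error(fitCalibration(data.frame(ratio = c(2, 1, 3, 0.5),
                                         ph = c(5, 6, 7, 8))),
               "monotonically increasing")
})

test_that("ratio-to-pH conversion interpolates and flags extrapolation", {
  cal <- simulateCalibrationSeries(noiseSd = 0)
  fit <- fitCalibration(cal)
  mid <- (max(cal$ratio) + min(cal$ratio)) / 2
  expect_equal(as.numeric(ratioToPh(fit, mid)),
               fit@intercept + fit@slope * mid)

  ## noise-free generator round trip stays within 0.02 pH in range
  phTrue <- seq(5.2, 7.3, by = 0.05)
  est <- ratioToPh(fit, intensity(ratioModel(), phTrue))
  expect_lt(max(abs(as.numeric(est) - phTrue)), 0.02)
  expect_false(any(attr(est, "outOfRange")))

  far <- ratioToPh(fit, intensity(ratioModel(), c(6, 8.6)))
  expect_equal(attr(far, "outOfRange"), c(FALSE, TRUE))
  expect_error(ratioToPh(fit, intensity(ratioModel(), c(9.5, 9.9))),
               "outside")
})

test_that("round-trip error grows with calibration noise", {
  phTrue <- seq(5.5, 7.0, by = 0.1)
  rmse <- vapply(c(0.002, 0.02), function(ns) {
    e <- vapply(1:20, function(s) {
      fit <- fitCalibration(simulateCalibrationSeries(noiseSd = ns,
                                                      seed = 100 + s))
      est <- as.numeric(ratioToPh(fit, intensity(ratioModel(), phTrue),
                                  margin = 2))
      sqrt(mean((est - phTrue)^2))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_gt(rmse[2], 3 * rmse[1])
})

test_that("peak detection finds prominent pulses only", {
  expect_equal(nrow(detectPeaks(rep(5.8, 100), seq(0, 198, 2))), 0)

  t <- seq(0, 300, 2)
  two <- 5.8 + 0.4 * exp(-(t - 80)^2 / (2 * 12^2)) +
    0.03 * exp(-(t - 220)^2 / (2 * 12^2))   # 0.03 < 0.25 * (p95 - p5)
  pk <- detectPeaks(two, t)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time, 80)

  coh <- simulateCohort(nCells = 20, seed = 91, channels = ratioChannels())
  gt <- groundTruth(coh)
  fit <- fitCalibration(simulateCalibrationSeries(seed = 92))
  hits <- vapply(seq_len(20), function(i) {
    ph <- as.numeric(ratioToPh(fit, channelValues(coh[[i]], "ratio")))
    nrow(detectPeaks(ph, traceTimes(coh[[i]]))) ==
      length(gt[[i]]$pulseTimes)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cycle metrics pair each peak with its preceding minimum", {
  t <- seq(0, 340, 2)
  tr <- 5.8 + 0.4 * exp(-(t - 100)^2 / 60) + 0.5 * exp(-(t - 250)^2 / 60)
  tr[t > 160 & t < 190] <- 5.8    # explicit inter-peak trough
  pk <- detectPeaks(tr, t)
  cm <- cycleMetrics(tr, pk, t)
  expect_equal(nrow(cm), 2)
  expect_equal(cm$peak_ph, c(6.2, 6.3), tolerance = 1e-6)
  expect_equal(cm$min_ph, c(5.8, 5.8), tolerance = 1e-3)
  expect_equal(cm$delta_ph, c(0.4, 0.5), tolerance = 1e-3)

  one <- 5.9 + c(rep(0, 40), 0.4 * exp(-(seq(-40, 40, 2))^2 / 80), rep(0, 40))
  tm <- seq_along(one) * 2
  pk1 <- detectPeaks(one, tm)
  cm1 <- cycleMetrics(one, pk1, tm)
  expect_equal(cm1$delta_ph, max(one) - 5.9, tolerance = 1e-9)
})

test_that("half-maximal widths follow pulse geometry", {
  ## triangular pulse, height 1, base width 20 min -> half width 10 min
  t <- seq(0, 200, 1)
  tri <- pmax(0, 1 - abs(t - 100) / 10)
  pk <- detectPeaks(tri, t)
  expect_equal(pk$half_width, 10, tolerance = 1e-9)

  ## Gaussian pulse of scale sigma -> 2 sqrt(2 log 2) sigma
  sigma <- 8
  g <- exp(-(t - 100)^2 / (2 * sigma^2))
  pkg <- detectPeaks(g, t)
  expect_equal(pkg$half_width, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.02)
  expect_equal(peakHalfwidthSummary(list(pk, pkg)),
               median(c(pk$half_width, pkg$half_width)))
})

test_that("stochastic-pulse cohorts show the short YNBD pulse width", {
  coh <- simulateCohort(nCells = 30, seed = 95,
                        profile = oscillationProfile("YNBD"),
                        channels = ratioChannels())
  fit <- fitCalibration(simulateCalibrationSeries(seed = 96))
  hw <- unlist(lapply(traces(coh), function(tr) {
    ph <- as.numeric(ratioToPh(fit, channelValues(tr, "ratio")))
    detectPeaks(ph, traceTimes(tr))$half_width
  }))
  ## 2-min pulses sampled at dt = 2: measured width is at the sampling
  ## floor, within one interval of the generating FWHM
  expect_lt(abs(median(hw) - 2), 2)
})

test_that("first-peak alignment shifts times and events together", {
  t <- seq(0, 340, 2)
  v <- 5.8 + 0.4 * exp(-(t - 137 - 1)^2 / 60)   # peak at t = 138 on grid
  tr <- traceSeries("a", t, list(ratio = v),
                    events = list(bud_emergence = c(80)))
  al <- alignFirstPeak(list(tr), channel = "ratio")
  expect_equal(traceTimes(al$traces[[1]])[1], -138)
  expect_equal(eventTimes(al$traces[[1]], "bud_emergence"), 80 - 138)
  expect_equal(al$nExcluded, 0)

  flat <- traceSeries("b", t, list(ratio = rep(5.8, length(t))))
  expect_warning(al2 <- alignFirstPeak(list(tr, flat), channel = "ratio"),
                 "excluded")
  expect_equal(al2$nExcluded, 1)
  expect_length(al2$traces, 1)
})

test_that("event intervals are simple differences around each peak", {
  t <- seq(0, 200, 2)
  v <- 5.8 + 0.4 * exp(-(t - 70)^2 / 60)
  tr <- traceSeries("a", t, list(ratio = v),
                    events = list(bud_emergence = c(10),
                                  separation = c(75)))
  iv <- eventIntervals(list(tr), channel = "ratio")
  expect_equal(iv$cycles$bud_to_peak, 60)
  expect_equal(iv$cycles$peak_to_sep, 5)

  ## peak coincident with separation -> zero interval
  tr2 <- traceSeries("b", t, list(ratio = v),
                     events = list(bud_emergence = c(10),
                                   separation = c(70)))
  expect_equal(eventIntervals(list(tr2), channel = "ratio")$cycles$peak_to_sep,
               0)

  ## missing events are skipped and counted
  tr3 <- traceSeries("c", t, list(ratio = v),
                     events = list(separation = c(75)))
  iv3 <- eventIntervals(list(tr3), channel = "ratio")
  expect_equal(nrow(iv3$cycles), 0)
  expect_equal(iv3$nUnmatched, 1)
})
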