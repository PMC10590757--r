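test_that("profile invariants are enforced", {
  expect_error(oscillationProfile(phPeak = 5.5), "phPeak")
  expect_error(oscillationProfile(pulseFwhm = 90), "pulseFwhm")
  expect_error(oscillationProfile(budToPeak = 80, peakToSep = 10),
               "budToPeak")
  expect_error(oscillationProfile(mode = "weird"), "mode")
})

test_that("regular mode places floor(duration/period) pulses at phase 0", {
  tr <- simulatePhTrace(oscillationProfile(period = 100, noiseSd = 0),
                        duration = 1000, dt = 2, seed = 1)
  expect_length(tr$truth$pulseTimes, 10)
  for (period in c(80, 85, 100, 125)) {
    tr <- simulatePhTrace(oscillationProfile(period = period, noiseSd = 0),
                          duration = 1000, dt = 2, seed = 1)
    expect_length(tr$truth$pulseTimes, floor(1000 / period))
  }
})

test_that("pulse extrema hit the configured baseline and peak pH", {
  tr <- simulatePhTrace(oscillationProfile(noiseSd = 0), seed = 1)
  expect_equal(unique(tr$truth$cycleMin), 5.82)
  expect_equal(unique(tr$truth$cyclePeak), 6.20)
  ## realized series: sampled extremes match the analytic ones to within
  ## the grid-sampling error of the 11-min pulse (< 0.01 pH at dt = 2)
  expect_lt(abs(min(tr$ph) - 5.82), 1e-3)
  expect_lt(abs(max(tr$ph) - 6.20), 1e-2)
})

test_that("degenerate profiles collapse to a constant baseline", {
  p <- oscillationProfile(phPeak = 5.82, phBase = 5.82, noiseSd = 0)
  tr <- simulatePhTrace(p, seed = 1)
  expect_equal(unique(tr$ph), 5.82)
  flat <- simulatePhTrace(oscillationProfile(mode = "flat", noiseSd = 0),
                          seed = 1)
  expect_equal(unique(flat$ph), 5.82)
  expect_length(flat$truth$pulseTimes, 0)
})

test_that("trace generation rejects bad sampling arguments", {
  expect_error(simulatePhTrace(oscillationProfile(), dt = 0), "positive")
  expect_error(simulatePhTrace(oscillationProfile(), duration = -5),
               "positive")
})

test_that("fluorophore titration follows the Henderson-Hasselbalch form", {
  m <- fluorophoreModel(pka = 6.1, hill = 1, iMax = 1)
  expect_equal(intensity(m, 6.1), 0.5)
  expect_equal(intensity(m, 7.1), 10 / 11)
  ref <- fluorophoreModel(iMax = 3, phSensitive = FALSE)
  expect_equal(applyFluorophore(c(4, 6, 8), ref), rep(3, 3))
  ## strictly increasing with limits 0 and iMax
  ph <- seq(2, 11, by = 0.25)
  v <- intensity(m, ph)
  expect_true(all(diff(v) > 0))
  expect_lt(v[1], 1e-3)
  expect_gt(v[length(v)], 1 - 1e-3)
})

test_that("ratio model passes through its midpoint", {
  rm <- ratioModel(rMin = 0.2, rMax = 2.2, pka = 6.98)
  expect_equal(intensity(rm, 6.98), (0.2 + 2.2) / 2)
  expect_true(all(diff(intensity(rm, seq(4, 9, 0.1))) > 0))
})

test_that("cohorts are pure functions of their seed", {
  a <- simulateCohort(nCells = 10, seed = 42)
  b <- simulateCohort(nCells = 10, seed = 42)
  expect_identical(lapply(traces(a), as.data.frame),
                   lapply(traces(b), as.data.frame))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- simulateCohort(nCells = 10, seed = 43)
  expect_false(identical(as.data.frame(a[[1]]), as.data.frame(c[[1]])))
})

test_that("cohort dimensions follow duration/dt and annotations are attached", {
  coh <- simulateCohort(nCells = 50, seed = 1)
  expect_length(traces(coh), 50)
  expect_true(all(vapply(traces(coh), function(tr)
    length(traceTimes(tr)) == 500, logical(1))))
  tr <- coh[[1]]
  gt <- groundTruth(coh)[[1]]
  expect_equal(eventTimes(tr, "bud_emergence"), gt$budTimes)
  expect_equal(eventTimes(tr, "separation"), gt$sepTimes)
  ## events sit at the configured offsets around each pulse
  full <- gt$pulseTimes[gt$pulseTimes >= 59.4]
  expect_equal(full - 59.4,
               eventTimes(tr, "bud_emergence")[seq_along(full)])
})

test_that("zero amplitude multiplier yields flat traces up to noise", {
  coh <- simulateCohort(nCells = 5, seed = 7, amplitudeMultiplier = 0)
  for (tr in traces(coh)) {
    v <- channelValues(tr, "vsep")
    expect_lt(diff(range(v)), 0.05)   # noise only, no 0.38-pH pulses
  }
})

test_that("calibration series match their model exactly at zero noise", {
  cal <- simulateCalibrationSeries(noiseSd = 0)
  expect_equal(nrow(cal), 6)
  expect_equal(cal$ph, seq(5, 7.5, 0.5))
  expect_equal(cal$ratio, intensity(ratioModel(), cal$ph))
  expect_error(simulateCalibrationSeries(grid = 5), "at least 2")
  expect_error(simulateCalibrationSeries(grid = c(6, 5.5)),
               "strictly increasing")
})

test_that("size cohorts honour both generating modes and their seed", {
  noiseless <- simulateSizeCohort(n = 40, noiseSd = 0, seed = 1)
  expect_equal(noiseless$rel_g1, log(60) - log(noiseless$v_birth))
  ## axis lengths reproduce the volumes through the ellipsoid formula
  expect_equal(ellipsoidVolume(noiseless$l_birth, noiseless$s_birth),
               noiseless$v_birth)
  lin <- simulateSizeCohort(n = 2000, mode = "linear", slope = 0,
                            intercept = 0.7, noiseSd = 0.1, seed = 2)
  f <- fitSizeControl(lin)
  expect_lt(abs(f@slope), 3 * f@se + 0.02)
  expect_identical(simulateSizeCohort(n = 20, seed = 9),
                   simulateSizeCohort(n = 20, seed = 9))
  expect_error(simulateSizeCohort(n = 2), "at least 3")
})

test_that("rendered scenes place cells as advertised", {
  ## empty scene: background-only frame
  empty <- new("TraceCohort", traces = list(), groundTruth = list(), dt = 2)
  sc <- renderImageStack(empty, sceneConfig(frameShape = c(64, 64),
                                            backgroundLevel = 5), seed = 1)
  expect_true(all(sc$stacks[[1]]@frames == 5))

  ## one static cell, no noise: disk mean equals the model intensity
  coh <- simulateCohort(nCells = 1, duration = 20, dt = 2, seed = 3,
                        profile = oscillationProfile(noiseSd = 0))
  r <- renderImageStack(coh, sceneConfig(frameShape = c(96, 96),
                                         cellMotionSd = 0), seed = 4)
  cx <- r$truth$centers[1, 1, 1]; cy <- r$truth$centers[1, 2, 1]
  for (t in c(1, 5, 10)) {
    fr <- r$stacks$vsep@frames[, , t]
    xs <- 1:96; ys <- 1:96
    mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= 13.5^2
    expect_equal(mean(fr[mask]), channelValues(coh[[1]], "vsep")[t])
  }
  ## renderer and detector agree on the default vacuole diameter
  expect_equal(sceneConfig()$vacuoleDiameter,
               eval(formals(detectVacuoles)$diameter))
})

test_that("overcrowded scenes fail with a placement error", {
  coh <- simulateCohort(nCells = 30, duration = 10, dt = 2, seed = 1)
  expect_error(renderImageStack(coh, sceneConfig(frameShape = c(64, 64)),
                                seed = 1), "non-overlapping")
})
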