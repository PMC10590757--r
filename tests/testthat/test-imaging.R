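## small helper to paint a disk into a matrix
paintDisk <- function(fr, cx, cy, radius, value) {
  xs <- seq_len(ncol(fr)); ys <- seq_len(nrow(fr))
  mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
  fr[mask] <- fr[mask] + value
  fr
}

test_that("background subtraction removes flats and matches the opening oracle", {
  flat <- matrix(7, 40, 40)
  expect_true(all(subtractBackground(flat, radius = 10) == 0))

  set.seed(5)
  img <- matrix(runif(48 * 48), 48, 48)
  img <- paintDisk(img, 24, 20, 6.5, 3)
  got <- subtractBackground(img, radius = 15)
  kern <- EBImage::makeBrush(31, shape = "disc")
  expect_equal(got, pmax(img - bruteOpening(img, kern), 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("background subtraction preserves blob contrast at default radius", {
  img <- matrix(10, 128, 128)            # flat background + 27-px disk
  img <- paintDisk(img, 64, 64, 13.5, 100)
  out <- subtractBackground(img, radius = 50)
  d2 <- outer((1:128 - 64)^2, (1:128 - 64)^2, "+")
  expect_lt(abs(mean(out[d2 <= 10^2]) - 100) / 100, 0.05)
  expect_lt(max(out[d2 > 16^2]), 5)
  expect_error(subtractBackground(img, radius = 100), "exceeds")
})

test_that("phase-correlation registration recovers constructed shifts", {
  set.seed(9)
  base <- matrix(runif(64 * 64), 64, 64)
  base <- paintDisk(base, 30, 28, 8, 4)
  same <- imageStack(list(base, base, base), dt = 2)
  expect_true(all(registerStack(same)$shifts[, c("dx", "dy")] == 0))

  moved <- imageStack(list(base, circShift(base, 3, -2)), dt = 2)
  reg <- registerStack(moved)
  expect_equal(reg$shifts$dx[2], 3)
  expect_equal(reg$shifts$dy[2], -2)
  expect_equal(getFrame(reg$stack, 1L), base)

  single <- imageStack(list(base), dt = 2)
  expect_equal(nrow(registerStack(single)$shifts), 1)
  ## registering an already-registered stack is a no-op
  rereg <- registerStack(reg$stack)
  expect_true(all(rereg$shifts[, c("dx", "dy")] == 0))
})

test_that("LoG detection localizes disks and rejects blank frames", {
  fr <- matrix(0, 96, 96)
  expect_equal(nrow(detectVacuoles(fr)), 0)

  fr <- paintDisk(fr, 40.5, 52.5, 13.5, 1)
  det <- detectVacuoles(fr, diameter = 27, threshold = 0.3)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x - 40.5)^2 + (det$y - 52.5)^2), 1.01)
  expect_gt(det$quality, 0.3)

  two <- paintDisk(paintDisk(matrix(0, 120, 120), 40, 60, 13.5, 1),
                   80, 60, 13.5, 1)
  expect_equal(nrow(detectVacuoles(two)), 2)

  bad <- fr; bad[3, 3] <- NA
  expect_error(detectVacuoles(bad), "non-finite")
  expect_error(detectVacuoles(fr, diameter = 2), "at least 3")
})

test_that("LoG response peaks when the filter scale matches the disk", {
  fr <- paintDisk(matrix(0, 128, 128), 64, 64, 13.5, 1)  # 27-px disk
  sweep <- c(17, 21, 27, 35, 41)
  q <- vapply(sweep, function(d) {
    det <- detectVacuoles(fr, diameter = d, threshold = 0.1)
    if (nrow(det)) max(det$quality) else 0
  }, numeric(1))
  expect_equal(sweep[which.max(q)], 27)
})

test_that("a static spot links into one full-length track", {
  det <- data.frame(frame = 0:9, x = 50, y = 50)
  tk <- linkTracks(det)
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(nrow(tk), 10)
  expect_equal(tk$frame, 0:9)
})

test_that("frame-to-frame assignment equals the brute-force minimum", {
  set.seed(21)
  for (rep in 1:25) {
    nT <- sample(1:5, 1); nD <- sample(1:5, 1)
    pred <- matrix(runif(nT * 2, 0, 100), nT, 2)
    det <- pred[sample(nT, min(nT, nD), replace = FALSE), , drop = FALSE]
    det <- det + matrix(rnorm(length(det), 0, 8), nrow(det), 2)
    if (nD > nrow(det))
      det <- rbind(det, matrix(runif((nD - nrow(det)) * 2, 0, 100),
                               ncol = 2))
    gates <- sample(c(20, 25), nT, replace = TRUE)
    lk <- vacuoscope:::.linkStep(pred, gates, det, radius = 20)
    oracle <- bruteLinkCost(pred, gates, det, radius = 20)
    expect_equal(linkStepCost(lk, pred, gates, det, 20), oracle$cost,
                 tolerance = 1e-9)
  }
})

test_that("motion prediction keeps crossing constant-velocity spots apart", {
  frames <- 0:10
  a <- data.frame(frame = frames, x = 10 + 8 * frames, y = 50)
  b <- data.frame(frame = frames, x = 90 - 8 * frames, y = 50)
  tk <- linkTracks(rbind(a, b))
  expect_equal(length(unique(tk$track_id)), 2)
  for (id in unique(tk$track_id)) {
    xs <- tk$x[tk$track_id == id]
    expect_equal(length(xs), 11)
    expect_true(all(abs(diff(xs)) == 8))   # velocity never flips
  }
})

test_that("a displacement beyond the gate terminates the track", {
  det <- data.frame(frame = 0:5, x = c(50, 50, 50, 80, 80, 80), y = 10)
  tk <- linkTracks(det, initialRadius = 25, radius = 20)
  expect_equal(length(unique(tk$track_id)), 2)
  expect_equal(range(tk$frame[tk$track_id == tk$track_id[1]]), c(0, 2))
})

test_that("trace extraction reads uniform fields and ratios faithfully", {
  fr <- matrix(6, 64, 64)
  stacks <- list(vsep = imageStack(list(fr, fr, fr), dt = 2),
                 mcherry = imageStack(list(fr / 2, fr / 2, fr / 2), dt = 2))
  tracks <- data.frame(track_id = 1, frame = 0:2, x = 32, y = 32,
                       radius = 10)
  tr <- extractTraces(tracks, stacks)[[1]]
  expect_equal(channelValues(tr, "vsep"), rep(6, 3))
  expect_equal(channelRatio(tr, "vsep", "mcherry"), rep(2, 3))
})

test_that("noise-free rendered cohorts round-trip through the image chain", {
  coh <- simulateCohort(nCells = 5, duration = 60, dt = 2, seed = 31,
                        profile = oscillationProfile(noiseSd = 0))
  r <- renderImageStack(coh, sceneConfig(frameShape = c(160, 160),
                                         cellMotionSd = 0.4), seed = 32)
  res <- trackStacks(r$stacks, bgRadius = NA, register = FALSE)
  expect_length(res$traces, 5)
  truthTraces <- lapply(traces(coh), channelValues, channel = "vsep")
  for (tr in res$traces) {
    got <- channelValues(tr, "vsep")
    relerr <- vapply(truthTraces, function(tt)
      max(abs(got - tt[seq_along(got)]) / tt[seq_along(got)]), numeric(1))
    expect_lt(min(relerr), 0.01)
    ## localization against ground-truth centers: < 1 px mean error
    tid <- as.integer(cellId(tr))
    tkrows <- res$tracks[res$tracks$track_id == tid, ]
    errs <- vapply(seq_len(nrow(tkrows)), function(k) {
      t <- tkrows$frame[k] + 1
      min(sqrt((r$truth$centers[, 1, t] - tkrows$x[k])^2 +
               (r$truth$centers[, 2, t] - tkrows$y[k])^2))
    }, numeric(1))
    expect_lt(mean(errs), 1)
  }
})
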