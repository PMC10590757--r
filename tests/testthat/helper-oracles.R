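## Independent oracles used across the suite. These deliberately use
## brute-force formulations so they share no code path with the package.

## grayscale opening (erosion then dilation) by direct min/max over a
## structuring-element mask; mirrors nothing of EBImage
bruteOpening <- function(img, kern) {
  kr <- (nrow(kern) - 1) / 2
  off <- which(kern == 1, arr.ind = TRUE) - kr - 1  # offsets, (dy, dx)
  nr <- nrow(img); nc <- ncol(img)
  apply1 <- function(src, f, pad) {
    out <- matrix(NA_real_, nr, nc)
    for (y in seq_len(nr)) for (x in seq_len(nc)) {
      ys <- y + off[, 1]; xs <- x + off[, 2]
      ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
      vals <- src[cbind(ys[ok], xs[ok])]
      if (any(!ok)) vals <- c(vals, pad)   # border: pad like EBImage
      out[y, x] <- f(vals)
    }
    out
  }
  er <- apply1(img, min, pad = max(img))
  apply1(er, max, pad = min(er))
}

## direct DFT summation (no FFT)
bruteDFT <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

## exhaustive frame-to-frame linking oracle: minimizes total cost over all
## one-to-one partial matchings, where an unmatched track costs its
## squared gate and an unmatched detection costs radius^2
bruteLinkCost <- function(pred, gates, det, radius) {
  nT <- nrow(pred); nD <- nrow(det)
  d2 <- outer(pred[, 1], det[, 1], "-")^2 +
        outer(pred[, 2], det[, 2], "-")^2
  best <- Inf; bestMatch <- NULL
  assignRec <- function(i, used, cost, match) {
    if (cost >= best) return()
    if (i > nT) {
      tot <- cost + sum(!used) * radius^2
      if (tot < best) { best <<- tot; bestMatch <<- match }
      return()
    }
    assignRec(i + 1, used, cost + gates[i]^2, match)  # track unmatched
    for (j in seq_len(nD)) {
      if (!used[j] && d2[i, j] <= gates[i]^2) {
        used[j] <- TRUE
        match2 <- match; match2[i] <- j
        assignRec(i + 1, used, cost + d2[i, j], match2)
        used[j] <- FALSE
      }
    }
  }
  assignRec(1, rep(FALSE, nD), 0, rep(NA_integer_, nT))
  list(cost = best, match = bestMatch)
}

## cost of a .linkStep result under the same objective
linkStepCost <- function(lk, pred, gates, det, radius) {
  d2 <- outer(pred[, 1], det[, 1], "-")^2 +
        outer(pred[, 2], det[, 2], "-")^2
  cost <- 0
  if (length(lk$track))
    cost <- sum(d2[cbind(lk$track, lk$detection)])
  unT <- setdiff(seq_len(nrow(pred)), lk$track)
  unD <- setdiff(seq_len(nrow(det)), lk$detection)
  cost + sum(gates[unT]^2) + length(unD) * radius^2
}

## Holm step-down by hand
bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m); out[o] <- adj
  out
}

## circular shift of a matrix (test-side twin for registration fixtures)
circShift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

## standard ratiometric ph cohort analysis used by several tests: fit a
## default calibration, convert, call peaks and cycles
phPipeline <- function(cohort, calSeed = 11) {
  fit <- fitCalibration(simulateCalibrationSeries(seed = calSeed))
  peaks <- list(); cycles <- list()
  for (tr in traces(cohort)) {
    ph <- as.numeric(ratioToPh(fit, channelValues(tr, "ratio")))
    pk <- detectPeaks(ph, traceTimes(tr))
    peaks[[cellId(tr)]] <- pk
    if (nrow(pk))
      cycles[[cellId(tr)]] <- cycleMetrics(ph, pk, traceTimes(tr))
  }
  list(fit = fit, peaks = peaks, cycles = do.call(rbind, cycles))
}
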