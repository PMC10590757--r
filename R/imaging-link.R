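#' @include AllClasses.R
NULL

.LAP_BIG <- 1e12

## internal: square linear assignment problem, shortest augmenting path
## with potentials (O(n^3)). `a` must be square and finite (use .LAP_BIG
## for forbidden pairs). Returns the column assigned to each row.
.solveLAP <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n == m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- cols[!used[cols + 1]]
      cur <- a[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1] <- j0
      jpos <- which.min(minv[free])
      j1 <- free[jpos]; delta <- minv[j1]
      usedCols <- which(used) - 1L
      for (j in usedCols) {
        u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
        v[j + 1] <- v[j + 1] - delta
      }
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

## internal: one frame-to-frame linking step as an augmented LAP
## (Jaqaman-style): matching a feasible pair always beats leaving both
## unmatched because the per-entity no-match cost is the squared gate.
.linkStep <- function(pred, gates, det, radius) {
  nT <- nrow(pred); nD <- nrow(det)
  if (nT == 0 || nD == 0)
    return(list(track = integer(0), detection = integer(0)))
  C <- matrix(.LAP_BIG, nT + nD, nT + nD)
  d2 <- outer(pred[, 1], det[, 1], "-")^2 + outer(pred[, 2], det[, 2], "-")^2
  feas <- d2 <= matrix(gates^2, nT, nD)
  top <- matrix(.LAP_BIG, nT, nD); top[feas] <- d2[feas]
  C[seq_len(nT), seq_len(nD)] <- top
  C[cbind(seq_len(nT), nD + seq_len(nT))] <- gates^2
  C[cbind(nT + seq_len(nD), seq_len(nD))] <- radius^2
  C[nT + seq_len(nD), nD + seq_len(nT)] <- 0
  asn <- .solveLAP(C)
  tr <- which(asn[seq_len(nT)] <= nD & feas[cbind(seq_len(nT),
                                                  pmin(asn[seq_len(nT)], nD))])
  list(track = tr, detection = asn[tr])
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame linking with constant-velocity motion prediction and
#' globally optimal one-to-one assignment (minimum total squared distance
#' to the predicted positions, solved as a linear assignment problem).
#' Single-point tracks are extended within `initialRadius` of their last
#' position (two-point track initiation); tracks with two or more points
#' predict `2 p_t - p_(t-1)` and are gated at `radius`. Unmatched
#' detections seed new tracks; a track terminates on its first miss (no
#' gap closing, splitting or merging).
#'
#' @param detections data frame with columns `frame` (0-based), `x`, `y`
#'   and optionally `radius`, `quality` (see [detectVacuoles()]).
#' @param initialRadius gate for the second point of a track, pixels
#'   (default 25).
#' @param radius gate for motion-predicted links, pixels (default 20).
#' @return data frame of track points: `track_id`, `frame`, `x`, `y`,
#'   plus any `radius`/`quality` columns carried through.
#' @export
linkTracks <- function(detections, initialRadius = 25, radius = 20) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (nrow(detections) == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  frames <- sort(unique(detections$frame))
  active <- list()   # each: list(id, x = numeric, y = numeric, rows = idx)
  done <- list()
  nextId <- 1L
  prevFrame <- NULL
  for (f in frames) {
    rows <- which(detections$frame == f)
    det <- cbind(detections$x[rows], detections$y[rows])
    if (!is.null(prevFrame) && f != prevFrame + 1) {
      done <- c(done, active); active <- list()   # temporal gap: no gap closing
    }
    if (length(active)) {
      pred <- t(vapply(active, function(tr) {
        np <- length(tr$x)
        if (np >= 2)
          c(2 * tr$x[np] - tr$x[np - 1], 2 * tr$y[np] - tr$y[np - 1])
        else c(tr$x[np], tr$y[np])
      }, numeric(2)))
      gates <- vapply(active, function(tr)
        if (length(tr$x) >= 2) radius else initialRadius, numeric(1))
      lk <- .linkStep(pred, gates, det, radius)
      matchedT <- lk$track; matchedD <- lk$detection
      for (k in seq_along(matchedT)) {
        i <- matchedT[k]; j <- matchedD[k]
        active[[i]]$x <- c(active[[i]]$x, det[j, 1])
        active[[i]]$y <- c(active[[i]]$y, det[j, 2])
        active[[i]]$rows <- c(active[[i]]$rows, rows[j])
      }
      missed <- setdiff(seq_along(active), matchedT)
      done <- c(done, active[missed])
      active <- active[setdiff(seq_along(active), missed)]
      newD <- setdiff(seq_len(nrow(det)), matchedD)
    } else newD <- seq_len(nrow(det))
    for (j in newD) {
      active[[length(active) + 1]] <-
        list(id = nextId, x = det[j, 1], y = det[j, 2], rows = rows[j])
      nextId <- nextId + 1L
    }
    prevFrame <- f
  }
  done <- c(done, active)
  out <- do.call(rbind, lapply(done, function(tr)
    cbind(track_id = tr$id, detections[tr$rows, , drop = FALSE])))
  rownames(out) <- NULL
  out[order(out$track_id, out$frame), ]
}
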