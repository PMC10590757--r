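#' @include AllClasses.R synthetic-traces.R
NULL

## internal: mean intensity in a disk; positions in 1-based pixel coords.
## Returns NA when the center lies outside the frame.
.diskMean <- function(fr, cx, cy, radius) {
  nr <- nrow(fr); nc <- ncol(fr)
  if (cx < 1 || cx > nc || cy < 1 || cy > nr) return(NA_real_)
  x0 <- max(1, floor(cx - radius)); x1 <- min(nc, ceiling(cx + radius))
  y0 <- max(1, floor(cy - radius)); y1 <- min(nr, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  sub <- fr[ys, xs, drop = FALSE]
  mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
  if (!any(mask)) return(fr[round(cy), round(cx)])
  mean(sub[mask])
}

#' Extract per-cell intensity traces from tracks and channel stacks
#'
#' For every track and frame, the mean intensity inside a disk centered
#' on the track position is measured in each channel stack. The
#' measurement disk is shrunk one pixel below `aperture` so that, under
#' sub-pixel localization error, it stays strictly inside the object and
#' the mean is not diluted by background rim pixels. Samples whose center
#' falls outside a frame are excluded (the longest contiguous valid run
#' is kept so sampling stays uniform). Tracks with fewer than
#' `minSamples` valid samples are dropped.
#'
#' @param tracks data frame from [linkTracks()].
#' @param stacks named list of co-registered [Stack-class] objects, one
#'   per channel, all of the same length.
#' @param aperture disk radius, pixels; default: the detection radius
#'   carried in `tracks` (or 13.5 if absent).
#' @param minSamples minimum valid samples per trace (default 2).
#' @return list of [TraceSeries-class], one per surviving track, with the
#'   track id as cell id.
#' @export
extractTraces <- function(tracks, stacks, aperture = NULL, minSamples = 2) {
  stopifnot(is.list(stacks), length(stacks) >= 1, !is.null(names(stacks)))
  lens <- vapply(stacks, nFrames, numeric(1))
  if (length(unique(lens)) != 1)
    stop("all channel stacks must have the same number of frames")
  dt <- stacks[[1]]@dt
  if (is.null(aperture))
    aperture <- if ("radius" %in% names(tracks)) tracks$radius[1] else 13.5
  aperture <- max(aperture - 1, 1)
  out <- list()
  for (id in unique(tracks$track_id)) {
    tk <- tracks[tracks$track_id == id, ]
    tk <- tk[order(tk$frame), ]
    vals <- sapply(names(stacks), function(ch) {
      st <- stacks[[ch]]
      vapply(seq_len(nrow(tk)), function(r)
        .diskMean(getFrame(st, tk$frame[r]), tk$x[r], tk$y[r], aperture),
        numeric(1))
    })
    vals <- matrix(vals, nrow = nrow(tk),
                   dimnames = list(NULL, names(stacks)))
    ok <- rowSums(is.na(vals)) == 0
    if (!all(ok)) {       # keep the longest contiguous valid run
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      runs <- which(r$values)
      if (!length(runs)) next
      best <- runs[which.max(r$lengths[runs])]
      keep <- (ends[best] - r$lengths[best] + 1):ends[best]
    } else keep <- seq_len(nrow(tk))
    if (length(keep) < minSamples) next
    out[[length(out) + 1]] <- traceSeries(
      cellId = as.character(id),
      times = tk$frame[keep] * dt,
      intensities = vals[keep, , drop = FALSE])
  }
  out
}

#' Run the full imaging chain on a set of channel stacks
#'
#' Convenience wrapper: background subtraction, registration (on the
#' tracking channel), detection, linking and trace extraction, using the
#' standard processing defaults (rolling-ball radius 50 px, LoG diameter
#' 27 px at threshold 0.3, linking radii 25/20 px).
#'
#' @param stacks named list of [Stack-class] objects.
#' @param trackChannel channel used for detection/tracking (default:
#'   first channel).
#' @param bgRadius rolling-ball radius, pixels; `NA` skips subtraction.
#' @param register logical; apply translational registration.
#' @param diameter,threshold,initialRadius,radius detector and linker
#'   parameters (see [detectVacuoles()], [linkTracks()]).
#' @return list with `traces` (list of [TraceSeries-class]), `tracks`,
#'   `detections` and `shifts`.
#' @export
trackStacks <- function(stacks, trackChannel = names(stacks)[1],
                        bgRadius = 50, register = TRUE, diameter = 27,
                        threshold = 0.3, initialRadius = 25, radius = 20) {
  if (!is.na(bgRadius))
    stacks <- lapply(stacks, subtractBackground, radius = bgRadius)
  shifts <- NULL
  if (register) {
    reg <- registerStack(stacks[[trackChannel]])
    shifts <- reg$shifts
    stacks[[trackChannel]] <- reg$stack
    for (ch in setdiff(names(stacks), trackChannel)) {
      out <- stacks[[ch]]@frames
      for (t in seq_len(nrow(shifts))[-1])
        out[, , t] <- .shiftFrame(out[, , t], -shifts$dx[t], -shifts$dy[t])
      stacks[[ch]] <- imageStack(out, dt = stacks[[ch]]@dt,
                                 channel = stacks[[ch]]@channel)
    }
  }
  det <- detectStack(stacks[[trackChannel]], diameter, threshold)
  tracks <- linkTracks(det, initialRadius, radius)
  list(traces = extractTraces(tracks, stacks),
       tracks = tracks, detections = det, shifts = shifts)
}
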