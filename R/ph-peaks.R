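#' @include AllClasses.R synthetic-traces.R
NULL

## internal: indices of local maxima, with plateau handling (a flat run
## counts once, at its center)
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1 || i == k) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
      out <- c(out, floor((starts[i] + ends[i]) / 2))
  }
  out
}

## internal: prominence of peak at index i (scipy convention: bases are
## the minima between the peak and the nearest higher point on each side,
## or the trace ends)
.prominence <- function(x, i) {
  h <- x[i]
  leftMin <- h
  j <- i - 1
  while (j >= 1 && x[j] <= h) { leftMin <- min(leftMin, x[j]); j <- j - 1 }
  rightMin <- h
  j <- i + 1
  n <- length(x)
  while (j <= n && x[j] <= h) { rightMin <- min(rightMin, x[j]); j <- j + 1 }
  h - max(leftMin, rightMin)
}

## internal: width of peak i at height h - prom/2, linear interpolation
## between samples; clipped at the trace ends
.halfWidth <- function(x, times, i, prom) {
  wh <- x[i] - prom / 2
  j <- i
  while (j > 1 && x[j - 1] >= wh) j <- j - 1
  tl <- if (j == 1) times[1] else {
    f <- (x[j] - wh) / (x[j] - x[j - 1])
    times[j] - f * (times[j] - times[j - 1])
  }
  n <- length(x)
  j <- i
  while (j < n && x[j + 1] >= wh) j <- j + 1
  tr <- if (j == n) times[n] else {
    f <- (x[j] - wh) / (x[j] - x[j + 1])
    times[j] + f * (times[j + 1] - times[j])
  }
  tr - tl
}

#' Detect alkalinization peaks in a pH (or intensity) trace
#'
#' Local maxima whose prominence is at least `minProminenceFrac` times
#' the trace's 5th-95th percentile range, thinned so that accepted peaks
#' are at least `minSeparation` minutes apart (stronger peaks win). The
#' half-maximal width of each peak is measured at half its prominence
#' with linear interpolation between samples.
#'
#' @param values numeric trace (uniform sampling) or a
#'   [TraceSeries-class] together with `channel`.
#' @param times sample times, minutes.
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   5-95 percentile range (default 0.25; robust to drift).
#' @param minSeparation minimum peak spacing, minutes (default 20, well
#'   below the shortest cell-cycle period).
#' @param channel channel name when `values` is a `TraceSeries`.
#' @return data frame of peaks ordered in time: `time`, `height`,
#'   `prominence`, `half_width`, `index`.
#' @export
detectPeaks <- function(values, times = NULL, minProminenceFrac = 0.25,
                        minSeparation = 20, channel = NULL) {
  if (is(values, "TraceSeries")) {
    times <- traceTimes(values)
    values <- channelValues(values,
                            if (is.null(channel)) channelNames(values)[1]
                            else channel)
  }
  if (is.null(times)) times <- seq_along(values)
  empty <- data.frame(time = numeric(0), height = numeric(0),
                      prominence = numeric(0), half_width = numeric(0),
                      index = integer(0))
  cand <- .localMaxima(values)
  if (!length(cand)) return(empty)
  qs <- stats::quantile(values, c(0.05, 0.95), names = FALSE)
  minProm <- minProminenceFrac * (qs[2] - qs[1])
  proms <- vapply(cand, function(i) .prominence(values, i), numeric(1))
  keep <- proms >= minProm & proms > 0
  cand <- cand[keep]; proms <- proms[keep]
  if (!length(cand)) return(empty)
  ord <- order(-values[cand])
  acc <- logical(length(cand))
  for (i in ord) {
    if (!any(acc & abs(times[cand] - times[cand[i]]) < minSeparation))
      acc[i] <- TRUE
  }
  cand <- cand[acc]; proms <- proms[acc]
  hw <- vapply(seq_along(cand), function(k)
    .halfWidth(values, times, cand[k], proms[k]), numeric(1))
  o <- order(times[cand])
  data.frame(time = times[cand][o], height = values[cand][o],
             prominence = proms[o], half_width = hw[o],
             index = cand[o])
}

#' Median half-maximal peak width over a cohort
#'
#' @param peaks a peaks data frame from [detectPeaks()], or a list of
#'   them (one per cell).
#' @return median of the per-peak half-maximal widths, minutes.
#' @export
peakHalfwidthSummary <- function(peaks) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  hw <- unlist(lapply(peaks, function(p) p$half_width))
  if (!length(hw)) stop("no peaks to summarize")
  stats::median(hw)
}

#' Align traces to their first detected peak
#'
#' Shifts each trace's time axis (and its event annotations) so its
#' first peak sits at t = 0. Traces without a detected peak are excluded
#' with a warning.
#'
#' @param traces list of [TraceSeries-class].
#' @param peaks list of peaks data frames ([detectPeaks()]), parallel to
#'   `traces`; computed with defaults when missing.
#' @param channel channel used when peaks must be computed.
#' @return list with `traces` (aligned) and `nExcluded`.
#' @export
alignFirstPeak <- function(traces, peaks = NULL, channel = NULL) {
  if (is.null(peaks))
    peaks <- lapply(traces, detectPeaks, channel = channel)
  out <- list(); excluded <- 0L
  for (i in seq_along(traces)) {
    pk <- peaks[[i]]
    if (nrow(pk) == 0) { excluded <- excluded + 1L; next }
    tr <- traces[[i]]
    shift <- pk$time[1]
    out[[length(out) + 1]] <- traceSeries(
      cellId(tr), traceTimes(tr) - shift, tr@intensities,
      events = lapply(tr@events, function(e) e - shift))
  }
  if (excluded > 0)
    warning(excluded, " trace(s) without a detected peak were excluded")
  list(traces = out, nExcluded = excluded)
}
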