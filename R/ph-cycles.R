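#' @include AllClasses.R ph-peaks.R
NULL

#' Per-cycle pH metrics
#'
#' For each detected peak, the cycle minimum is the minimum of the trace
#' on the interval from the previous peak (or the trace start) up to the
#' current peak, so each minimum precedes its peak; `delta_ph` is the
#' alkalinization amplitude `peak - min` of that cycle.
#'
#' @param values numeric pH trace (or a [TraceSeries-class] with
#'   `channel`).
#' @param peaks peaks data frame from [detectPeaks()] (at least one
#'   peak).
#' @param times sample times, minutes.
#' @param channel channel name when `values` is a `TraceSeries`.
#' @return data frame, one row per cycle in time order: `peak_time`,
#'   `peak_ph`, `min_ph`, `delta_ph`.
#' @export
cycleMetrics <- function(values, peaks, times = NULL, channel = NULL) {
  if (is(values, "TraceSeries")) {
    times <- traceTimes(values)
    values <- channelValues(values,
                            if (is.null(channel)) channelNames(values)[1]
                            else channel)
  }
  if (is.null(times)) times <- seq_along(values)
  if (nrow(peaks) < 1) stop("cycleMetrics requires at least one peak")
  idx <- sort(peaks$index)
  out <- data.frame(peak_time = numeric(0), peak_ph = numeric(0),
                    min_ph = numeric(0), delta_ph = numeric(0))
  prev <- 1L
  for (i in idx) {
    m <- min(values[prev:i])
    out[nrow(out) + 1, ] <- c(times[i], values[i], m, values[i] - m)
    prev <- i
  }
  out
}

#' Time detected peaks against annotated cell-cycle events
#'
#' For every detected peak with both a preceding bud-emergence
#' annotation and a following cell-separation annotation, computes
#' `bud_to_peak = peak_time - nearest preceding bud emergence` and
#' `peak_to_sep = nearest following separation - peak_time`. Peaks
#' without both events are skipped and counted.
#'
#' @param traces list of annotated [TraceSeries-class] (events
#'   `bud_emergence` and `separation`), or a [TraceCohort-class].
#' @param peaks list of peaks data frames parallel to `traces`; computed
#'   with [detectPeaks()] defaults when missing.
#' @param channel channel used when peaks must be computed.
#' @return list with `cycles` (data frame: `cell_id`, `peak_time`,
#'   `bud_to_peak`, `peak_to_sep`), `summary` (means, sd and s.e.m.) and
#'   `nUnmatched`.
#' @export
eventIntervals <- function(traces, peaks = NULL, channel = NULL) {
  if (is(traces, "TraceCohort")) traces <- traces(traces)
  if (is.null(peaks))
    peaks <- lapply(traces, detectPeaks, channel = channel)
  rows <- list(); unmatched <- 0L
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    bud <- eventTimes(tr, "bud_emergence")
    sep <- eventTimes(tr, "separation")
    for (tp in peaks[[i]]$time) {
      b <- bud[bud <= tp]
      s <- sep[sep >= tp]
      if (!length(b) || !length(s)) { unmatched <- unmatched + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cellId(tr), peak_time = tp,
        bud_to_peak = tp - max(b), peak_to_sep = min(s) - tp)
    }
  }
  cycles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), peak_time = numeric(0),
               bud_to_peak = numeric(0), peak_to_sep = numeric(0))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    interval = c("bud_to_peak", "peak_to_sep"),
    mean = c(mean(cycles$bud_to_peak), mean(cycles$peak_to_sep)),
    sd = c(stats::sd(cycles$bud_to_peak), stats::sd(cycles$peak_to_sep)),
    sem = c(sem(cycles$bud_to_peak), sem(cycles$peak_to_sep)),
    n = nrow(cycles))
  list(cycles = cycles, summary = summary, nUnmatched = unmatched)
}
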