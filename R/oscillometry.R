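#' @include AllClasses.R synthetic-traces.R
NULL

#' Select traces long enough for spectral analysis
#'
#' Keeps traces whose time span (last minus first sample time) is at
#' least `minSpan` minutes; the threshold is inclusive.
#'
#' @param traces list of [TraceSeries-class].
#' @param minSpan minimum span, minutes (default 500).
#' @return the surviving subset (possibly empty).
#' @export
selectTraces <- function(traces, minSpan = 500) {
  traces[vapply(traces, traceSpan, numeric(1)) >= minSpan]
}

#' Remove a linear time trend
#'
#' Subtracts the ordinary-least-squares line (intercept + slope * time) so
#' slow drifts in brightness do not leak into the low-frequency end of the
#' spectrum; the residual has zero mean and zero OLS slope.
#'
#' @param values numeric series (at least 3 samples).
#' @param times optional sample times; defaults to the sample index.
#' @return detrended numeric series.
#' @export
detrendTrace <- function(values, times = seq_along(values)) {
  if (length(values) < 3) stop("need at least 3 samples to detrend")
  stats::lm.fit(cbind(1, times), values)$residuals
}

#' Periodogram of a detrended trace
#'
#' `P(k) = |sum_t x_t exp(-2 pi i k t / n)|^2 / n` for
#' `k = 1 .. floor(n/2)` at frequencies `f_k = k / (n dt)`. With this
#' scaling a pure sinusoid of intensity amplitude `A` on `n` samples
#' carries power `A^2 n / 4` at its frequency, and the spectrum satisfies
#' the Parseval identity
#' `P(0) + P(n/2) + 2 sum_(k=1)^(n/2-1) P(k) = sum_t x_t^2` (even `n`).
#'
#' @param values detrended numeric series, `n >= 4` samples.
#' @param dt sampling interval, minutes.
#' @return a [Periodogram-class].
#' @export
periodogram <- function(values, dt = 2) {
  n <- length(values)
  if (n < 4) stop("need at least 4 samples")
  if (any(!is.finite(values))) stop("values must be finite")
  X <- stats::fft(values)
  P <- Mod(X)^2 / n
  k <- seq_len(floor(n / 2))
  new("Periodogram", freq = k / (n * dt), power = P[k + 1], n = n, dt = dt)
}

#' Dominant oscillatory component of a periodogram
#'
#' The oscillatory amplitude is the maximal spectral power and the
#' dominant period is `n dt / k` at the argmax. Ties are broken toward
#' the smallest `k` (the longest period). An all-zero spectrum is flagged
#' with amplitude 0 and an undefined period.
#'
#' @param pg a [Periodogram-class].
#' @return a [DominantComponent-class].
#' @export
dominantComponent <- function(pg) {
  stopifnot(is(pg, "Periodogram"))
  if (length(pg@power) == 0) stop("empty periodogram")
  if (all(pg@power == 0))
    return(new("DominantComponent", amplitude = 0, period = NA_real_,
               k = NA_real_, flagged = TRUE))
  k <- which.max(pg@power)   # which.max takes the first (smallest k) tie
  new("DominantComponent", amplitude = pg@power[k],
      period = pg@n * pg@dt / k, k = k, flagged = FALSE)
}

setMethod("show", "Periodogram", function(object) {
  cat(sprintf("Periodogram: %d frequencies (n = %d, dt = %.3g min)\n",
              length(object@freq), object@n, object@dt))
})

setMethod("show", "DominantComponent", function(object) {
  if (object@flagged)
    cat("DominantComponent: flat spectrum (amplitude 0, period undefined)\n")
  else
    cat(sprintf("DominantComponent: amplitude %.4g AU^2, period %.2f min (k = %d)\n",
                object@amplitude, object@period, object@k))
})

#' Per-cell dominant components for a cohort
#'
#' The population spectral pipeline: select traces with at least
#' `minSpan` minutes of data, detrend each cell's channel signal, compute
#' its periodogram and record the dominant amplitude and period.
#'
#' @param traces list of [TraceSeries-class] (or a [TraceCohort-class]).
#' @param channel channel to analyze (default `"vsep"`); use a ratio via
#'   `numerator`/`denominator` by passing `channel = "ratio"` when such a
#'   channel exists, or precompute with [channelRatio()].
#' @param minSpan selection threshold, minutes.
#' @return data frame: `cell_id`, `amplitude_au2`, `period_min`, `k`.
#' @export
quantifyCohort <- function(traces, channel = "vsep", minSpan = 500) {
  if (is(traces, "TraceCohort")) traces <- traces(traces)
  kept <- selectTraces(traces, minSpan)
  rows <- lapply(kept, function(tr) {
    x <- detrendTrace(channelValues(tr, channel), traceTimes(tr))
    dc <- dominantComponent(periodogram(x, dt = diff(traceTimes(tr)[1:2])))
    data.frame(cell_id = cellId(tr), amplitude_au2 = dc@amplitude,
               period_min = dc@period, k = dc@k)
  })
  if (!length(rows))
    return(data.frame(cell_id = character(0), amplitude_au2 = numeric(0),
                      period_min = numeric(0), k = numeric(0)))
  do.call(rbind, rows)
}
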