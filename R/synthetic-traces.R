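#' @include AllClasses.R AllGenerics.R fluorophore.R
NULL

#' Construct a TraceSeries
#'
#' @param cellId character identifier.
#' @param times sample times, minutes (uniform spacing).
#' @param intensities numeric matrix (rows = time points) or named list of
#'   equal-length numeric vectors, one per channel.
#' @param events named list of event-time vectors, e.g.
#'   `list(bud_emergence = c(...), separation = c(...))`.
#' @return a [TraceSeries-class].
#' @export
traceSeries <- function(cellId, times, intensities, events = list()) {
  if (is.list(intensities) && !is.matrix(intensities))
    intensities <- do.call(cbind, intensities)
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, ncol = 1,
                          dimnames = list(NULL, "ch1"))
  storage.mode(intensities) <- "double"
  new("TraceSeries", cellId = as.character(cellId),
      times = as.numeric(times), intensities = intensities,
      events = events)
}

#' @rdname TraceSeries-class
#' @export
setMethod("cellId", "TraceSeries", function(object) object@cellId)

#' @rdname TraceSeries-class
#' @export
setMethod("traceTimes", "TraceSeries", function(object) object@times)

#' @rdname TraceSeries-class
#' @export
setMethod("channelNames", "TraceSeries",
          function(object) colnames(object@intensities))

#' @rdname TraceSeries-class
#' @export
setMethod("channelValues", "TraceSeries", function(object, channel) {
  if (!channel %in% colnames(object@intensities))
    stop("no channel '", channel, "' in trace ", object@cellId)
  object@intensities[, channel]
})

#' @rdname TraceSeries-class
#' @param event event name, e.g. `"bud_emergence"`.
#' @export
setMethod("eventTimes", "TraceSeries", function(object, event) {
  ev <- object@events[[event]]
  if (is.null(ev)) numeric(0) else ev
})

#' @rdname TraceSeries-class
#' @export
setMethod("traceSpan", "TraceSeries", function(object) {
  diff(range(object@times))
})

setMethod("show", "TraceSeries", function(object) {
  cat(sprintf("TraceSeries '%s': %d samples, dt %.3g min, channels: %s\n",
              object@cellId, length(object@times),
              if (length(object@times) > 1) diff(object@times[1:2]) else NA,
              paste(colnames(object@intensities), collapse = ", ")))
  if (length(object@events))
    cat("  events:", paste(sprintf("%s (%d)", names(object@events),
                                   lengths(object@events)),
                           collapse = ", "), "\n")
})

#' @export
#' @describeIn TraceSeries-class long-format data frame
#'   (`cell_id`, `time_min`, one `ch_<name>` column per channel).
setMethod("as.data.frame", "TraceSeries", function(x, ...) {
  d <- data.frame(cell_id = x@cellId, time_min = x@times,
                  x@intensities, check.names = FALSE)
  names(d)[-(1:2)] <- paste0("ch_", colnames(x@intensities))
  d
})

#' Ratio of two channels of a trace
#'
#' @param trace a [TraceSeries-class].
#' @param numerator,denominator channel names.
#' @return numeric vector of per-sample ratios.
#' @export
channelRatio <- function(trace, numerator = "vsep",
                         denominator = "mcherry") {
  channelValues(trace, numerator) / channelValues(trace, denominator)
}

#' @rdname TraceCohort-class
#' @export
setMethod("traces", "TraceCohort", function(object) object@traces)

#' @rdname TraceCohort-class
#' @export
setMethod("groundTruth", "TraceCohort", function(object) object@groundTruth)

#' @rdname TraceCohort-class
#' @export
setMethod("length", "TraceCohort", function(x) length(x@traces))

#' @rdname TraceCohort-class
#' @param i index.
#' @export
setMethod("[[", "TraceCohort", function(x, i) x@traces[[i]])

setMethod("show", "TraceCohort", function(object) {
  cat(sprintf("TraceCohort: %d cells, dt %.3g min%s\n",
              length(object@traces), object@dt,
              if (length(object@groundTruth)) ", with ground truth" else ""))
})

## internal: pulse maxima for one cell. Regular mode places one pulse per
## period at phase + k*period (k >= 1 when phase == 0, so a 1000-min trace
## with a 100-min period carries exactly 10 pulses); stochastic mode draws
## a Poisson process. Consumes the current RNG stream.
.pulseTimes <- function(profile, duration, phase) {
  if (profile@mode == "flat") return(numeric(0))
  if (profile@mode == "regular") {
    k <- seq_len(ceiling(duration / profile@period) + 1)
    t0 <- if (phase > 0) phase + (k - 1) * profile@period
          else k * profile@period
    t0[t0 > 0 & t0 <= duration]
  } else {
    n <- stats::rpois(1, profile@pulseRate * duration)
    sort(stats::runif(n, 0, duration))
  }
}

## internal: noise-free pH signal from pulse times (Gaussian pulses of the
## given FWHM riding on baseline + drift)
.phSignal <- function(profile, times, pulseTimes, pulseHeight) {
  ph <- profile@phBase + profile@driftRate * times
  if (length(pulseTimes) && pulseHeight != 0) {
    sig <- profile@pulseFwhm / (2 * sqrt(2 * log(2)))
    for (tp in pulseTimes)
      ph <- ph + pulseHeight * exp(-(times - tp)^2 / (2 * sig^2))
  }
  ph
}

#' Simulate one cell's vacuolar pH trajectory with ground truth
#'
#' Generates a uniformly sampled pH series following an
#' [OscillationProfile-class]: Gaussian alkalinization pulses of height
#' `(phPeak - phBase) * amplitudeMultiplier` on an acidic baseline, with
#' per-sample Gaussian noise, plus the ground truth needed to verify any
#' downstream estimate (pulse times, event times, noise-free series,
#' per-cycle true extrema).
#'
#' @param profile an [OscillationProfile-class].
#' @param duration trace length, minutes; `duration / dt` must be integral.
#' @param dt sampling interval, minutes.
#' @param seed optional integer seed (the generator is a pure function of
#'   profile + seed).
#' @param phase time of the first pulse, minutes; with `phase = 0` pulses
#'   sit at `period, 2 period, ...` so a trace holds
#'   `floor(duration / period)` pulses.
#' @param amplitudeMultiplier cohort-level scale on the pulse contrast.
#' @return a list with `times`, `ph` (noisy series) and `truth` (a list:
#'   `pulseTimes`, `budTimes`, `sepTimes`, `period`, `phTrue`,
#'   `cyclePeak`, `cycleMin`).
#' @examples
#' tr <- simulatePhTrace(oscillationProfile(noiseSd = 0), seed = 1)
#' range(tr$truth$cycleMin)  # 5.82
#' @export
simulatePhTrace <- function(profile, duration = 1000, dt = 2, seed = NULL,
                            phase = 0, amplitudeMultiplier = 1) {
  stopifnot(is(profile, "OscillationProfile"))
  validObject(profile)
  if (dt <= 0 || duration <= 0) stop("duration and dt must be positive")
  if (duration < dt) stop("duration must be at least dt")
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    stop("duration must be an integer multiple of dt")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration - dt, by = dt)
  pulses <- .pulseTimes(profile, duration, phase)
  height <- (profile@phPeak - profile@phBase) * amplitudeMultiplier
  phTrue <- .phSignal(profile, times, pulses, height)
  ph <- phTrue + stats::rnorm(length(times), 0, profile@noiseSd)
  bud <- pulses - profile@budToPeak
  sep <- pulses + profile@peakToSep
  truth <- list(
    pulseTimes = pulses,
    budTimes = bud[bud >= 0 & bud <= duration],
    sepTimes = sep[sep >= 0 & sep <= duration],
    period = profile@period,
    phTrue = phTrue,
    cyclePeak = if (length(pulses))
      profile@phBase + profile@driftRate * pulses + height else numeric(0),
    cycleMin = if (length(pulses))
      profile@phBase + profile@driftRate *
        pmax(pulses - profile@period / 2, 0) else numeric(0)
  )
  list(times = times, ph = ph, truth = truth)
}

#' Default reporter channels (pH-sensitive v-SEP-like + mCherry reference)
#'
#' @return named list of channel models.
#' @export
defaultChannels <- function() {
  list(vsep = fluorophoreModel(pka = 6.1, hill = 1, iMax = 1),
       mcherry = fluorophoreModel(iMax = 1, phSensitive = FALSE))
}

#' Ratiometric dye channel set (BCECF-like)
#'
#' @return named list with a single `ratio` channel.
#' @export
ratioChannels <- function() list(ratio = ratioModel())

#' Simulate a cohort of annotated fluorescence traces
#'
#' Each cell receives an independent pulse phase (uniform over one period)
#' and independent noise; the pH series is pushed through every channel
#' model to give the intensity matrix, and bud-emergence / separation
#' annotations are attached from the profile's event offsets. Fully
#' reproducible from the seed.
#'
#' @param nCells number of cells.
#' @param duration,dt trace length and sampling interval, minutes
#'   (defaults 1000 and 2: 500 samples per cell).
#' @param seed integer seed.
#' @param profile an [OscillationProfile-class].
#' @param channels named list of channel models
#'   (see [defaultChannels()], [ratioChannels()]).
#' @param amplitudeMultiplier cohort-level pulse-contrast scale
#'   (see [amplitudeMultiplierPreset()]).
#' @return a [TraceCohort-class] with per-cell ground truth.
#' @examples
#' coh <- simulateCohort(nCells = 3, seed = 1)
#' coh[[1]]
#' @export
simulateCohort <- function(nCells = 50, duration = 1000, dt = 2, seed = 1,
                           profile = oscillationProfile(),
                           channels = defaultChannels(),
                           amplitudeMultiplier = 1) {
  stopifnot(nCells >= 1, length(channels) >= 1,
            !is.null(names(channels)))
  set.seed(seed)
  out <- vector("list", nCells)
  gt <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    phase <- if (profile@mode == "regular")
      stats::runif(1, 0, profile@period) else 0
    tr <- simulatePhTrace(profile, duration, dt, seed = NULL,
                          phase = phase,
                          amplitudeMultiplier = amplitudeMultiplier)
    ints <- lapply(channels, intensity, ph = tr$ph)
    id <- sprintf("cell_%03d", i)
    out[[i]] <- traceSeries(
      id, tr$times, ints,
      events = list(bud_emergence = tr$truth$budTimes,
                    separation = tr$truth$sepTimes))
    gt[[i]] <- tr$truth
    gt[[i]]$cellId <- id
  }
  names(gt) <- vapply(out, cellId, character(1))
  new("TraceCohort", traces = out, groundTruth = gt, dt = dt)
}

#' Simulate an in-situ calibration series
#'
#' Measured ratio at each buffer pH of the grid, from a ratio model plus
#' Gaussian noise. The default grid spans pH 5.0-7.5 in 0.5-unit steps
#' (6 points), the standard in-situ buffer ladder.
#'
#' @param model a [RatioModel-class] (or a pH-sensitive
#'   [FluorophoreModel-class] whose response is divided by `reference`).
#' @param grid strictly increasing buffer pH values.
#' @param noiseSd Gaussian noise on the measured ratio.
#' @param seed optional integer seed.
#' @param reference optional pH-insensitive [FluorophoreModel-class]
#'   denominator when `model` is a fluorophore.
#' @return data frame with columns `ph` and `ratio`.
#' @export
simulateCalibrationSeries <- function(model = ratioModel(),
                                      grid = seq(5, 7.5, by = 0.5),
                                      noiseSd = 0.003, seed = NULL,
                                      reference = NULL) {
  if (length(grid) < 2) stop("calibration grid needs at least 2 points")
  if (any(diff(grid) <= 0)) stop("calibration grid must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  r <- intensity(model, grid)
  if (!is.null(reference)) r <- r / intensity(reference, grid)
  data.frame(ph = grid,
             ratio = r + stats::rnorm(length(grid), 0, noiseSd))
}
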