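#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' OscillationProfile: the per-cell vacuolar pH program
#'
#' Describes one cell's vacuolar pH trajectory as an acidic baseline with
#' transient alkalinization pulses, one per cell cycle in `regular` mode,
#' Poisson-timed in `stochastic_pulses` mode, absent in `flat` mode. The
#' pulse is Gaussian in time, parameterized by its full width at half
#' maximum. Cell-cycle events (bud emergence, cell separation) are tied to
#' each pulse maximum by fixed offsets.
#'
#' @slot phBase acidic baseline pH between pulses.
#' @slot phPeak pH at the pulse maximum.
#' @slot period minutes per cell cycle (regular mode pulse spacing).
#' @slot pulseFwhm full width at half maximum of the alkaline pulse, minutes.
#' @slot budToPeak minutes from bud emergence to the pulse maximum.
#' @slot peakToSep minutes from the pulse maximum to cell separation.
#' @slot driftRate slow linear baseline drift, pH per minute.
#' @slot mode one of `"regular"`, `"stochastic_pulses"`, `"flat"`.
#' @slot noiseSd additive Gaussian measurement noise per sample, pH units.
#' @slot pulseRate pulses per minute for `stochastic_pulses` mode.
#' @exportClass OscillationProfile
setClass("OscillationProfile",
  representation(
    phBase = "numeric", phPeak = "numeric", period = "numeric",
    pulseFwhm = "numeric", budToPeak = "numeric", peakToSep = "numeric",
    driftRate = "numeric", mode = "character", noiseSd = "numeric",
    pulseRate = "numeric"
  )
)

setValidity("OscillationProfile", function(object) {
  msg <- character()
  if (object@phPeak < object@phBase)
    msg <- c(msg, "phPeak must be >= phBase")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (object@pulseFwhm >= object@period)
    msg <- c(msg, "pulseFwhm must be smaller than period")
  if (object@budToPeak + object@peakToSep > object@period)
    msg <- c(msg, "budToPeak + peakToSep must not exceed period")
  if (!object@mode %in% c("regular", "stochastic_pulses", "flat"))
    msg <- c(msg, "mode must be regular, stochastic_pulses or flat")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@pulseRate <= 0) msg <- c(msg, "pulseRate must be positive")
  if (length(msg)) msg else TRUE
})

#' FluorophoreModel: pH titration response of a fluorophore
#'
#' Intensity follows the Henderson-Hasselbalch sigmoid
#' `I(pH) = iMax / (1 + 10^(hill * (pka - pH)))` when `phSensitive`, and is
#' constant `iMax` otherwise (a reference channel such as mCherry).
#'
#' @slot pka titration midpoint, pH units.
#' @slot hill cooperativity (steepness), dimensionless.
#' @slot iMax intensity at full deprotonation, arbitrary units.
#' @slot phSensitive logical; `FALSE` models a pH-insensitive reference.
#' @exportClass FluorophoreModel
setClass("FluorophoreModel",
  representation(pka = "numeric", hill = "numeric", iMax = "numeric",
                 phSensitive = "logical")
)

setValidity("FluorophoreModel", function(object) {
  msg <- character()
  if (object@iMax <= 0) msg <- c(msg, "iMax must be positive")
  if (object@phSensitive && object@hill <= 0)
    msg <- c(msg, "hill must be positive for a pH-sensitive fluorophore")
  if (length(msg)) msg else TRUE
})

#' RatioModel: ratiometric dye response
#'
#' The measured excitation ratio of a vacuole-sequestered ratiometric dye
#' (e.g. BCECF) as a saturating monotone function of pH:
#' `R(pH) = rMin + (rMax - rMin) / (1 + 10^(hill * (pka - pH)))`.
#' At `pH = pka` the ratio equals `(rMin + rMax) / 2`.
#'
#' @slot rMin ratio at full protonation.
#' @slot rMax ratio at full deprotonation.
#' @slot pka apparent titration midpoint, pH units.
#' @slot hill effective steepness; small values give a near-linear
#'   response across the calibration window.
#' @exportClass RatioModel
setClass("RatioModel",
  representation(rMin = "numeric", rMax = "numeric", pka = "numeric",
                 hill = "numeric")
)

setValidity("RatioModel", function(object) {
  msg <- character()
  if (object@rMax <= object@rMin) msg <- c(msg, "rMax must exceed rMin")
  if (object@hill <= 0) msg <- c(msg, "hill must be positive")
  if (length(msg)) msg else TRUE
})

setClassUnion("ChannelModel", c("FluorophoreModel", "RatioModel"))

#' TraceSeries: one cell's time-stamped channel intensities
#'
#' The common currency between the imaging, oscillometry and pH modules:
#' uniformly sampled per-channel intensities for one tracked cell, with
#' optional cell-cycle event annotations.
#'
#' @slot cellId character identifier.
#' @slot times sample times in minutes, strictly increasing, uniform step.
#' @slot intensities numeric matrix, one row per time point, one named
#'   column per channel.
#' @slot events named list of numeric event-time vectors (minutes), e.g.
#'   `bud_emergence`, `separation`.
#' @exportClass TraceSeries
setClass("TraceSeries",
  representation(cellId = "character", times = "numeric",
                 intensities = "matrix", events = "list")
)

setValidity("TraceSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 2) msg <- c(msg, "need at least two time points")
  if (n >= 2) {
    dts <- diff(object@times)
    if (any(dts <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (diff(range(dts)) > 1e-8 * max(dts))
      msg <- c(msg, "times must be uniformly spaced")
  }
  if (nrow(object@intensities) != n)
    msg <- c(msg, "intensities must have one row per time point")
  if (is.null(colnames(object@intensities)))
    msg <- c(msg, "intensity channels must be named")
  if (any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' TraceCohort: a set of TraceSeries plus simulation ground truth
#'
#' @slot traces list of [TraceSeries-class] objects.
#' @slot groundTruth per-cell ground truth (pulse times, event times, true
#'   pH series, per-cycle extrema) for synthetic cohorts; empty otherwise.
#' @slot dt sampling interval, minutes.
#' @exportClass TraceCohort
setClass("TraceCohort",
  representation(traces = "list", groundTruth = "list", dt = "numeric")
)

setValidity("TraceCohort", function(object) {
  ok <- vapply(object@traces, is, logical(1), class2 = "TraceSeries")
  if (!all(ok)) "all elements of traces must be TraceSeries" else TRUE
})

#' Stack: an ordered stack of single-channel frames
#'
#' @slot frames numeric array `nrow x ncol x nframes`; frame `i` (0-based
#'   index `i - 1`) is at time `(i - 1) * dt` minutes.
#' @slot dt minutes between frames.
#' @slot channel channel name.
#' @exportClass Stack
setClass("Stack",
  representation(frames = "array", dt = "numeric", channel = "character")
)

setValidity("Stack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "frames must be a 3-d array (rows x cols x frames)")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' Periodogram: the power spectrum of a detrended trace
#'
#' `P(k) = |sum_t x_t exp(-2 pi i k t / n)|^2 / n` at the Fourier
#' frequencies `f_k = k / (n dt)`, `k = 1 .. floor(n/2)`.
#'
#' @slot freq frequencies, cycles per minute.
#' @slot power spectral power, squared intensity units.
#' @slot n sample count of the input trace.
#' @slot dt sampling interval, minutes.
#' @exportClass Periodogram
setClass("Periodogram",
  representation(freq = "numeric", power = "numeric", n = "numeric",
                 dt = "numeric")
)

setValidity("Periodogram", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@power))
    msg <- c(msg, "freq and power must have equal length")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DominantComponent: the maximal (amplitude, period) of a periodogram
#'
#' @slot amplitude power at the dominant frequency (the oscillatory
#'   amplitude in squared intensity units).
#' @slot period `n * dt / k` at the argmax, minutes; `NA` when flagged.
#' @slot k the Fourier index of the maximum.
#' @slot flagged `TRUE` when the spectrum was all-zero and the period is
#'   undefined.
#' @exportClass DominantComponent
setClass("DominantComponent",
  representation(amplitude = "numeric", period = "numeric", k = "numeric",
                 flagged = "logical")
)

#' CalibrationFit: linear map from ratiometric signal to pH
#'
#' `pH = intercept + slope * ratio`, valid over the pH range spanned by
#' the calibration buffers.
#'
#' @slot intercept,slope coefficients of the standard curve.
#' @slot phRange numeric length-2: the buffer pH range of validity.
#' @slot residualSd residual standard deviation of the fit, pH units.
#' @slot n number of calibration points.
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(intercept = "numeric", slope = "numeric",
                 phRange = "numeric", residualSd = "numeric", n = "numeric")
)

setValidity("CalibrationFit", function(object) {
  if (object@slope <= 0)
    "slope must be positive (ratio increases with pH)" else TRUE
})

#' SizeControlFit: regression of relative G1 growth on log birth volume
#'
#' @slot slope,intercept OLS coefficients; a slope of -1 is the signature
#'   of a sizer (fixed volume at Start).
#' @slot se standard error of the slope.
#' @slot p two-sided t-test p-value for slope = 0.
#' @slot r2 coefficient of determination.
#' @slot n number of cells.
#' @exportClass SizeControlFit
setClass("SizeControlFit",
  representation(slope = "numeric", intercept = "numeric", se = "numeric",
                 p = "numeric", r2 = "numeric", n = "numeric")
)

#' SlopeComparison: nested-model F-test for equal slopes
#'
#' Compares a common-slope model (separate intercepts) against separate
#' slopes; `F` has `(1, n1 + n2 - 4)` degrees of freedom.
#'
#' @slot statistic the F statistic.
#' @slot df numeric length-2 degrees of freedom.
#' @slot p p-value.
#' @exportClass SlopeComparison
setClass("SlopeComparison",
  representation(statistic = "numeric", df = "numeric", p = "numeric")
)

setValidity("SlopeComparison", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "F must be non-negative")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
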