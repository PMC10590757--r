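#' @include AllClasses.R AllGenerics.R
NULL

#' Fit an in-situ pH standard curve
#'
#' Ordinary-least-squares fit of buffer pH on the measured ratio. The
#' standard curve is linear by default (the dye's ratio is near-linear in
#' pH well inside its titration range); the fit's validity range is the
#' span of the buffer pH values. Requires at least 4 points spanning at
#' least 1.5 pH units with a strictly increasing mean ratio trend.
#'
#' @param series data frame with columns `ph` (buffer pH) and `ratio`
#'   (measured pH-sensitive / pH-insensitive ratio).
#' @return a [CalibrationFit-class].
#' @examples
#' cal <- simulateCalibrationSeries(noiseSd = 0, seed = 1)
#' fitCalibration(cal)
#' @export
fitCalibration <- function(series) {
  stopifnot(all(c("ph", "ratio") %in% names(series)))
  if (nrow(series) < 4)
    stop("calibration requires at least 4 points")
  if (any(!is.finite(series$ratio)))
    stop("calibration ratios must be finite")
  if (diff(range(series$ph)) < 1.5)
    stop("calibration must span at least 1.5 pH units")
  ## reject series whose overall trend is not increasing (rank
  ## correlation of per-buffer mean ratio with pH); isolated noise
  ## inversions between adjacent buffers are tolerated
  means <- tapply(series$ratio, series$ph, mean)
  phLevels <- as.numeric(names(means))
  if (stats::cor(phLevels, means[order(phLevels)],
                 method = "kendall") <= 0)
    stop("calibration mean trend is not monotonically increasing")
  fit <- stats::lm(ph ~ ratio, data = series)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("calibration slope is not positive")
  new("CalibrationFit",
      intercept = unname(stats::coef(fit)[1]), slope = slope,
      phRange = range(series$ph),
      residualSd = stats::sigma(fit), n = nrow(series))
}

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: pH = %.4g + %.4g * ratio  (valid pH %.2f-%.2f, resid sd %.3g, n = %d)\n",
    object@intercept, object@slope, object@phRange[1], object@phRange[2],
    object@residualSd, object@n))
})

#' @describeIn ratioToPh convert a ratio trace to absolute pH
#'
#' Pointwise `intercept + slope * ratio`. Samples mapping more than
#' `margin` pH units outside the calibration range are flagged (attribute
#' `outOfRange`, a logical vector); if every sample is out of range the
#' conversion errors.
#'
#' @param margin extrapolation allowance beyond the calibrated pH range
#'   (default 0.25 units).
#' @export
setMethod("ratioToPh", "CalibrationFit", function(fit, ratio,
                                                  margin = 0.25) {
  ph <- fit@intercept + fit@slope * ratio
  oor <- ph < fit@phRange[1] - margin | ph > fit@phRange[2] + margin
  if (all(oor)) stop("all samples map outside the calibrated pH range")
  attr(ph, "outOfRange") <- oor
  ph
})
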