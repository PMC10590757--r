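#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an oscillation profile, optionally from a growth-medium preset
#'
#' Defaults describe the wild-type SDC condition: acidic baseline pH 5.82,
#' per-cycle alkalinization peaking at pH 6.20, an 85-min cell cycle, an
#' 11-min-wide (FWHM) alkaline pulse whose maximum falls 59.4 min after bud
#' emergence and 5.7 min before cell separation. Presets:
#' \describe{
#'   \item{SDC}{glucose + amino acids: regular per-cycle pulses (defaults).}
#'   \item{YNBD}{glucose without amino acids: no cell-cycle-linked
#'     oscillation; brief (2-min FWHM) stochastic alkalinization pulses at
#'     a Poisson rate of one per nominal period.}
#'   \item{SCEG}{glycerol/ethanol + amino acids: regular pulses as in SDC
#'     (the larger oscillation amplitude of this medium is applied at the
#'     cohort level, see [amplitudeMultiplierPreset()]).}
#' }
#'
#' @param medium optional preset, one of `"SDC"`, `"YNBD"`, `"SCEG"`.
#' @param phBase,phPeak baseline and pulse-maximum pH.
#' @param period minutes per cell cycle.
#' @param pulseFwhm pulse full width at half maximum, minutes.
#' @param budToPeak,peakToSep event offsets around the pulse maximum, min.
#' @param driftRate slow baseline drift, pH/min.
#' @param mode `"regular"`, `"stochastic_pulses"` or `"flat"`.
#' @param noiseSd per-sample Gaussian noise on the pH trace, pH units.
#' @param pulseRate Poisson pulse rate (stochastic mode), pulses/min.
#' @return an [OscillationProfile-class].
#' @examples
#' oscillationProfile()           # SDC defaults
#' oscillationProfile("YNBD")     # stochastic 2-min pulses
#' @export
oscillationProfile <- function(medium = c("SDC", "YNBD", "SCEG"),
                               phBase = 5.82, phPeak = 6.20, period = 85,
                               pulseFwhm = 11, budToPeak = 59.4,
                               peakToSep = 5.7, driftRate = 0,
                               mode = "regular", noiseSd = 0.005,
                               pulseRate = 1 / period) {
  medium <- match.arg(medium)
  if (medium == "YNBD" && missing(mode)) mode <- "stochastic_pulses"
  if (medium == "YNBD" && missing(pulseFwhm)) pulseFwhm <- 2
  new("OscillationProfile",
      phBase = phBase, phPeak = phPeak, period = period,
      pulseFwhm = pulseFwhm, budToPeak = budToPeak, peakToSep = peakToSep,
      driftRate = driftRate, mode = mode, noiseSd = noiseSd,
      pulseRate = pulseRate)
}

#' Per-medium oscillation contrast multiplier
#'
#' Cohort-level scale factor applied to the pulse contrast. SCEG cohorts
#' carry `sqrt(1.8)` so that their periodogram power (proportional to the
#' squared pulse height) is 1.8-fold that of SDC, the population-level
#' contrast between the respiratory and fermentative media.
#'
#' @param medium one of `"SDC"`, `"YNBD"`, `"SCEG"`.
#' @return a dimensionless multiplier.
#' @export
amplitudeMultiplierPreset <- function(medium = c("SDC", "YNBD", "SCEG")) {
  switch(match.arg(medium), SDC = 1, YNBD = 1, SCEG = sqrt(1.8))
}

#' Construct a fluorophore titration model
#'
#' @param pka titration midpoint, pH units.
#' @param hill cooperativity.
#' @param iMax intensity at full deprotonation, AU.
#' @param phSensitive set `FALSE` for a pH-insensitive reference channel.
#' @return a [FluorophoreModel-class].
#' @export
fluorophoreModel <- function(pka = 6.1, hill = 1, iMax = 1,
                             phSensitive = TRUE) {
  new("FluorophoreModel", pka = pka, hill = hill, iMax = iMax,
      phSensitive = phSensitive)
}

#' Construct a ratiometric dye model
#'
#' Defaults model a vacuole-sequestered dual-excitation dye (BCECF-like,
#' apparent pKa 6.98) whose ratio is close to linear in pH across the
#' 5.0-7.5 calibration window; the shallow steepness (`hill = 0.1`) keeps
#' the lack-of-fit of a linear standard curve below 0.01 pH units over the
#' vacuolar operating range while preserving the monotone saturating shape.
#'
#' @param rMin,rMax ratio limits at full protonation/deprotonation.
#' @param pka apparent midpoint, pH units.
#' @param hill effective steepness.
#' @return a [RatioModel-class].
#' @export
ratioModel <- function(rMin = 0.2, rMax = 2.2, pka = 6.98, hill = 0.1) {
  new("RatioModel", rMin = rMin, rMax = rMax, pka = pka, hill = hill)
}

#' @rdname intensity
#' @export
setMethod("intensity", "FluorophoreModel", function(object, ph) {
  stopifnot(is.numeric(ph))
  if (!object@phSensitive) return(rep(object@iMax, length(ph)))
  object@iMax / (1 + 10^(object@hill * (object@pka - ph)))
})

#' @rdname intensity
#' @export
setMethod("intensity", "RatioModel", function(object, ph) {
  stopifnot(is.numeric(ph))
  object@rMin + (object@rMax - object@rMin) /
    (1 + 10^(object@hill * (object@pka - ph)))
})

#' Apply a fluorophore (or ratio) model to a pH series
#'
#' Pointwise application of the titration equation; a pH-insensitive
#' reference model yields a constant series.
#'
#' @param ph numeric pH series.
#' @param model a [FluorophoreModel-class] or [RatioModel-class].
#' @return numeric intensity (or ratio) series.
#' @export
applyFluorophore <- function(ph, model) {
  stopifnot(is(model, "ChannelModel"))
  intensity(model, ph)
}

setMethod("show", "OscillationProfile", function(object) {
  cat(sprintf(
    "OscillationProfile [%s]: pH %.2f -> %.2f, period %.1f min, FWHM %.1f min\n",
    object@mode, object@phBase, object@phPeak, object@period,
    object@pulseFwhm))
  cat(sprintf("  bud->peak %.1f min, peak->sep %.1f min, noise sd %.3f pH\n",
              object@budToPeak, object@peakToSep, object@noiseSd))
})

setMethod("show", "FluorophoreModel", function(object) {
  if (object@phSensitive)
    cat(sprintf("FluorophoreModel: pKa %.2f, hill %.2f, iMax %.3g\n",
                object@pka, object@hill, object@iMax))
  else
    cat(sprintf("FluorophoreModel: pH-insensitive reference, iMax %.3g\n",
                object@iMax))
})

setMethod("show", "RatioModel", function(object) {
  cat(sprintf("RatioModel: ratio %.2f-%.2f, apparent pKa %.2f, hill %.2f\n",
              object@rMin, object@rMax, object@pka, object@hill))
})
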