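#' @include AllClasses.R
NULL

#' Evaluate a channel model at given pH values
#'
#' For a [FluorophoreModel-class] this is the Henderson-Hasselbalch
#' titration curve (or the constant `iMax` for a reference channel); for a
#' [RatioModel-class] it is the saturating ratio response.
#'
#' @param object a channel model.
#' @param ph numeric vector of pH values.
#' @return numeric vector of intensities (or ratios).
#' @examples
#' m <- fluorophoreModel(pka = 6.1, hill = 1, iMax = 1)
#' intensity(m, 6.1)  # exactly iMax / 2
#' @export
setGeneric("intensity", function(object, ph) standardGeneric("intensity"))

#' @rdname TraceCohort-class
#' @param object,x a `TraceCohort`.
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))

#' @rdname TraceCohort-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname TraceSeries-class
#' @param object a `TraceSeries`.
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname TraceSeries-class
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname TraceSeries-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname TraceSeries-class
#' @param channel channel name (column of the intensity matrix).
#' @export
setGeneric("channelValues",
           function(object, channel) standardGeneric("channelValues"))

#' @rdname TraceSeries-class
#' @export
setGeneric("eventTimes", function(object, event) standardGeneric("eventTimes"))

#' @rdname TraceSeries-class
#' @export
setGeneric("traceSpan", function(object) standardGeneric("traceSpan"))

#' @rdname Stack-class
#' @param object a `Stack`.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname Stack-class
#' @param i frame index, 0-based.
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))

#' Convert pH-calibrated signal using a fitted standard curve
#'
#' @param fit a [CalibrationFit-class].
#' @param ratio numeric vector of measured ratios.
#' @param ... further arguments.
#' @export
setGeneric("ratioToPh", function(fit, ratio, ...) standardGeneric("ratioToPh"))
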