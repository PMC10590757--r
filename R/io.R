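#' @include AllClasses.R synthetic-traces.R synthetic-images.R
NULL

#' Write traces (and annotations) to CSV
#'
#' Traces go to a long-format CSV with columns `cell_id`, `time_min` and
#' one `ch_<name>` column per channel; annotations (if any) to a second
#' CSV with columns `cell_id`, `event`, `time_min`.
#'
#' @param traces list of [TraceSeries-class] or a [TraceCohort-class].
#' @param file traces CSV path.
#' @param annotationsFile optional annotations CSV path.
#' @return `file`, invisibly.
#' @export
writeTraces <- function(traces, file, annotationsFile = NULL) {
  if (is(traces, "TraceCohort")) traces <- traces(traces)
  tab <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(tab, file, row.names = FALSE)
  if (!is.null(annotationsFile)) {
    ann <- do.call(rbind, lapply(traces, function(tr) {
      evs <- tr@events[lengths(tr@events) > 0]
      if (!length(evs)) return(NULL)
      data.frame(cell_id = cellId(tr),
                 event = rep(names(evs), lengths(evs)),
                 time_min = unlist(evs, use.names = FALSE))
    }))
    if (!is.null(ann)) utils::write.csv(ann, annotationsFile,
                                        row.names = FALSE)
  }
  invisible(file)
}

#' Read traces (and annotations) from CSV
#'
#' @param file traces CSV (`cell_id`, `time_min`, `ch_*` columns).
#' @param annotationsFile optional annotations CSV (`cell_id`, `event`,
#'   `time_min`).
#' @return list of [TraceSeries-class].
#' @export
readTraces <- function(file, annotationsFile = NULL) {
  tab <- utils::read.csv(file, check.names = FALSE)
  chCols <- grep("^ch_", names(tab), value = TRUE)
  if (!length(chCols)) stop("no ch_* channel columns in ", file)
  ann <- if (!is.null(annotationsFile) && file.exists(annotationsFile))
    utils::read.csv(annotationsFile) else NULL
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    ints <- as.matrix(d[chCols])
    dimnames(ints) <- list(NULL, sub("^ch_", "", chCols))
    evs <- list()
    if (!is.null(ann)) {
      a <- ann[ann$cell_id == d$cell_id[1], ]
      evs <- split(a$time_min, a$event)
    }
    traceSeries(d$cell_id[1], d$time_min, ints, events = evs)
  })
}

#' Read a calibration series CSV (`ph`, `ratio` columns)
#'
#' @param file CSV path.
#' @return data frame with `ph` and `ratio`.
#' @export
readCalibration <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("ph", "ratio") %in% names(d)))
    stop("calibration CSV needs columns 'ph' and 'ratio'")
  d
}

#' Read cell-size records from CSV
#'
#' Accepts either axis lengths (`l_birth`, `s_birth`, `l_bud`, `s_bud`,
#' micrometers) or precomputed volumes (`v_birth`, `v_bud`).
#'
#' @param file CSV path.
#' @param usePi volume prefactor mode, see [ellipsoidVolume()].
#' @return size-record data frame.
#' @export
readSizeRecords <- function(file, usePi = FALSE) {
  d <- utils::read.csv(file)
  if (!all(c("v_birth", "v_bud") %in% names(d))) {
    need <- c("l_birth", "s_birth", "l_bud", "s_bud")
    if (!all(need %in% names(d)))
      stop("size CSV needs axis-length or volume columns")
    d$v_birth <- ellipsoidVolume(d$l_birth, d$s_birth, usePi)
    d$v_bud <- ellipsoidVolume(d$l_bud, d$s_bud, usePi)
  }
  d
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages. Intensities are scaled
#' into `[0, 1]` by the stack maximum on write; the scale, sampling
#' interval and channel name are written to a JSON sidecar
#' (`<file>.json`) and restored on read when the sidecar is present.
#'
#' @param stack a [Stack-class].
#' @param file TIFF path.
#' @return `file` (write) or a [Stack-class] (read).
#' @export
writeStackTIFF <- function(stack, file) {
  stopifnot(is(stack, "Stack"))
  scale <- max(stack@frames, 1e-12)
  pages <- lapply(seq_len(nFrames(stack)), function(i)
    pmin(pmax(getFrame(stack, i - 1L) / scale, 0), 1))
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, dt = stack@dt,
                            channel = stack@channel),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeStackTIFF
#' @param dt,channel stack metadata, used when the file has no JSON
#'   sidecar.
#' @export
readStackTIFF <- function(file, dt = 2, channel = "ch1") {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$scale; dt <- meta$dt; channel <- meta$channel
  }
  frames <- lapply(pages, function(p) {
    attributes(p) <- list(dim = dim(p))
    p * scale
  })
  imageStack(frames, dt = dt, channel = channel)
}
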