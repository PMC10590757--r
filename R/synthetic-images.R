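#' @include AllClasses.R AllGenerics.R synthetic-traces.R
NULL

#' Construct a Stack
#'
#' @param frames 3-d numeric array (`rows x cols x frames`) or list of
#'   equal-shape matrices.
#' @param dt minutes between frames.
#' @param channel channel name.
#' @return a [Stack-class].
#' @export
imageStack <- function(frames, dt = 2, channel = "ch1") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  new("Stack", frames = frames, dt = dt, channel = channel)
}

#' @rdname Stack-class
#' @export
setMethod("nFrames", "Stack", function(object) dim(object@frames)[3])

#' @rdname Stack-class
#' @export
setMethod("getFrame", "Stack", function(object, i) {
  object@frames[, , i + 1L]
})

setMethod("show", "Stack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Stack '%s': %d frames of %d x %d px, dt %.3g min\n",
              object@channel, d[3], d[1], d[2], object@dt))
})

#' Image scene configuration for the synthetic renderer
#'
#' @param frameShape integer length-2, frame rows and columns, pixels.
#' @param vacuoleDiameter rendered vacuole diameter, pixels (default 27,
#'   matching the default blob-detector diameter).
#' @param cellMotionSd per-frame random-walk step s.d., pixels.
#' @param backgroundLevel constant background, AU.
#' @param backgroundGradient optional linear spatial gradient, AU per
#'   pixel along columns.
#' @param poissonNoise apply Poisson shot noise.
#' @param readNoiseSd additive Gaussian read noise s.d., AU.
#' @return a validated list of scene parameters.
#' @export
sceneConfig <- function(frameShape = c(192, 192), vacuoleDiameter = 27,
                        cellMotionSd = 0.5, backgroundLevel = 0,
                        backgroundGradient = 0, poissonNoise = FALSE,
                        readNoiseSd = 0) {
  if (vacuoleDiameter < 3) stop("vacuoleDiameter must be at least 3 px")
  if (length(frameShape) != 2 || any(frameShape < vacuoleDiameter))
    stop("frameShape must be two dimensions larger than the vacuole")
  list(frameShape = as.integer(frameShape),
       vacuoleDiameter = vacuoleDiameter, cellMotionSd = cellMotionSd,
       backgroundLevel = backgroundLevel,
       backgroundGradient = backgroundGradient,
       poissonNoise = poissonNoise, readNoiseSd = readNoiseSd)
}

## internal: non-overlapping initial placement; errors past the retry budget
.placeCells <- function(n, shape, radius, minSep, retries = 2000) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  pos <- matrix(NA_real_, n, 2)
  margin <- radius + 2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(retries)) {
      cand <- c(stats::runif(1, margin, shape[2] - margin),  # x (col)
                stats::runif(1, margin, shape[1] - margin))  # y (row)
      if (i == 1 ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                 2, cand)^2))) >= minSep) {
        pos[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping cells in a ",
                  shape[1], " x ", shape[2], " frame")
  }
  pos
}

#' Render synthetic timelapse image stacks from a trace cohort
#'
#' Each cell is drawn as a uniform disk of the configured diameter whose
#' interior value at frame `t` equals that cell's channel intensity at the
#' matching time (so the mean interior intensity equals the trace value
#' before background and noise). Cells random-walk between frames; Poisson
#' shot noise is applied first, then Gaussian read noise. Ground-truth
#' centers are stored per frame.
#'
#' @param cohort a [TraceCohort-class] (e.g. from [simulateCohort()]).
#' @param scene a [sceneConfig()] list.
#' @param seed integer seed.
#' @return list with `stacks` (named list of [Stack-class], one per
#'   channel) and `truth` (list: `centers`, an `nCells x 2 x nFrames`
#'   array of (x, y) positions in 1-based pixel coordinates).
#' @export
renderImageStack <- function(cohort, scene = sceneConfig(), seed = 1) {
  stopifnot(is(cohort, "TraceCohort"))
  set.seed(seed)
  trs <- traces(cohort)
  nCells <- length(trs)
  nT <- if (nCells) length(traceTimes(trs[[1]])) else 0
  if (nCells && nT == 0) stop("cohort traces are empty")
  shape <- scene$frameShape
  radius <- scene$vacuoleDiameter / 2
  channels <- if (nCells) channelNames(trs[[1]]) else character(0)
  if (nCells == 0) {
    nT <- 1L
    channels <- "background"
  }
  pos0 <- .placeCells(nCells, shape, radius,
                      minSep = scene$vacuoleDiameter * 1.3)
  centers <- array(NA_real_, c(max(nCells, 1), 2, nT))
  margin <- radius + 2
  pos <- pos0
  for (t in seq_len(nT)) {
    if (nCells && t > 1 && scene$cellMotionSd > 0) {
      pos <- pos + matrix(stats::rnorm(nCells * 2, 0, scene$cellMotionSd),
                          nCells, 2)
      pos[, 1] <- pmin(pmax(pos[, 1], margin), shape[2] - margin)
      pos[, 2] <- pmin(pmax(pos[, 2], margin), shape[1] - margin)
    }
    if (nCells) centers[, , t] <- pos
  }
  bg <- scene$backgroundLevel + scene$backgroundGradient *
    matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  stacks <- list()
  for (ch in channels) {
    frames <- array(0, c(shape[1], shape[2], nT))
    for (t in seq_len(nT)) {
      fr <- bg
      for (i in seq_len(nCells)) {
        v <- channelValues(trs[[i]], ch)[t]
        cx <- centers[i, 1, t]; cy <- centers[i, 2, t]
        xs <- max(1, floor(cx - radius)):min(shape[2], ceiling(cx + radius))
        ys <- max(1, floor(cy - radius)):min(shape[1], ceiling(cy + radius))
        mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
        sub <- fr[ys, xs, drop = FALSE]
        sub[mask] <- sub[mask] + v
        fr[ys, xs] <- sub
      }
      if (scene$poissonNoise)
        fr <- matrix(stats::rpois(length(fr), pmax(fr, 0)),
                     shape[1], shape[2])
      if (scene$readNoiseSd > 0)
        fr <- fr + stats::rnorm(length(fr), 0, scene$readNoiseSd)
      frames[, , t] <- fr
    }
    stacks[[ch]] <- imageStack(frames, dt = cohort@dt, channel = ch)
  }
  list(stacks = stacks,
       truth = list(centers = centers,
                    cellIds = vapply(trs, cellId, character(1))))
}
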