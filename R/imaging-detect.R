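#' @include AllClasses.R synthetic-images.R
NULL

## internal: FFT convolution with a centered, circularly wrapped
## scale-normalized LoG kernel (sigma^2 * Laplacian of Gaussian)
.logResponse <- function(frame, sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)]
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)]
  r2 <- outer(ky^2, kx^2, "+")
  ker <- (r2 / sigma^2 - 2) / (2 * pi * sigma^2) * exp(-r2 / (2 * sigma^2))
  Re(stats::fft(stats::fft(frame) * stats::fft(ker), inverse = TRUE)) /
    length(frame)
}

#' Blob detection by scale-normalized Laplacian of Gaussian
#'
#' The frame is min-max normalized, filtered with a scale-normalized LoG
#' at `sigma = diameter / (2 sqrt(2))` (the optimal scale for a disk of
#' that diameter), and the response negated so bright blobs score
#' positively. Local maxima of the negated response exceeding `threshold`
#' are returned; the quality is the response height, which for an ideal
#' full-contrast disk of matching diameter is `2/e` (~0.74), so the
#' default threshold of 0.3 is dimensionless and portable across
#' acquisitions.
#'
#' @param frame numeric matrix (one image frame); all pixels finite.
#' @param diameter estimated blob diameter, pixels (default 27).
#' @param threshold quality threshold on the normalized response
#'   (default 0.3).
#' @param frameIndex 0-based frame index stored in the output.
#' @return data frame of detections: `frame`, `x` (column), `y` (row),
#'   `radius`, `quality`. Pixel coordinates are 1-based.
#' @export
detectVacuoles <- function(frame, diameter = 27, threshold = 0.3,
                           frameIndex = 0L) {
  stopifnot(is.matrix(frame))
  if (any(!is.finite(frame))) stop("frame contains non-finite pixels")
  if (diameter < 3) stop("diameter must be at least 3 pixels")
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      radius = numeric(0), quality = numeric(0))
  rng <- range(frame)
  if (diff(rng) == 0) return(empty)
  norm <- (frame - rng[1]) / diff(rng)
  sigma <- diameter / (2 * sqrt(2))
  resp <- -.logResponse(norm, sigma)
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(empty)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  ismax <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & core >= resp[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  y <- idx[, 1] + 1L; x <- idx[, 2] + 1L
  q <- resp[cbind(y, x)]
  ## non-maximum suppression within one blob radius (plateau/dual maxima)
  ord <- order(-q)
  keep <- logical(length(ord))
  minSep2 <- (diameter / 2)^2
  for (i in ord) {
    if (!any(keep & ((x - x[i])^2 + (y - y[i])^2) < minSep2))
      keep[i] <- TRUE
  }
  ix <- x[keep]; iy <- y[keep]; q <- q[keep]
  ## sub-pixel refinement: 1-d parabola through the response and its
  ## neighbours along each axis (offset clamped to half a pixel)
  subpix <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (rm1 - rp1) / den))
  }
  x <- as.numeric(ix); y <- as.numeric(iy)
  for (k in seq_along(ix)) {
    if (ix[k] > 1 && ix[k] < nc)
      x[k] <- ix[k] + subpix(resp[iy[k], ix[k] - 1], q[k],
                             resp[iy[k], ix[k] + 1])
    if (iy[k] > 1 && iy[k] < nr)
      y[k] <- iy[k] + subpix(resp[iy[k] - 1, ix[k]], q[k],
                             resp[iy[k] + 1, ix[k]])
  }
  data.frame(frame = as.integer(frameIndex), x = x, y = y,
             radius = diameter / 2, quality = q)[order(-q), ]
}

#' Detect blobs in every frame of a stack
#'
#' @param stack a [Stack-class].
#' @inheritParams detectVacuoles
#' @return data frame of detections across frames (see [detectVacuoles()]).
#' @export
detectStack <- function(stack, diameter = 27, threshold = 0.3) {
  stopifnot(is(stack, "Stack"))
  nT <- dim(stack@frames)[3]
  out <- vector("list", nT)
  for (t in seq_len(nT))
    out[[t]] <- detectVacuoles(stack@frames[, , t], diameter, threshold,
                               frameIndex = t - 1L)
  do.call(rbind, out)
}
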