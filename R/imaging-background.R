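#' @include AllClasses.R synthetic-images.R
NULL

#' Rolling-ball background subtraction
#'
#' Per-frame morphological background removal: the background is estimated
#' by a grayscale opening with a disc structuring element of the given
#' radius (the disc-approximated "rolling ball") and subtracted; negative
#' residuals are clipped to zero. A constant frame is removed entirely;
#' objects smaller than the disc are preserved.
#'
#' @param stack a [Stack-class] (or a single matrix).
#' @param radius structuring-element radius, pixels (default 50).
#' @return object of the same kind as the input, background-subtracted.
#' @export
subtractBackground <- function(stack, radius = 50) {
  if (radius < 1) stop("radius must be at least 1 pixel")
  one <- function(fr) {
    if (2 * radius + 1 > min(dim(fr)))
      stop("radius (", radius, " px) exceeds the frame size")
    rng <- range(fr)
    if (diff(rng) == 0) return(array(0, dim(fr)))
    kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
    ## EBImage grayscale morphology expects intensities in [0, 1]
    bg <- EBImage::opening((fr - rng[1]) / diff(rng), kern) * diff(rng) +
      rng[1]
    pmax(fr - bg, 0)
  }
  if (is.matrix(stack)) return(one(stack))
  stopifnot(is(stack, "Stack"))
  out <- stack@frames
  for (t in seq_len(dim(out)[3])) out[, , t] <- one(out[, , t])
  imageStack(out, dt = stack@dt, channel = stack@channel)
}
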