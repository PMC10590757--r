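#' @include AllClasses.R synthetic-images.R
NULL

## internal: integer-pixel translation between two frames by phase
## correlation. Returns c(dx, dy) such that `moving` is `reference`
## translated by +dx columns and +dy rows (circularly).
.phaseShift <- function(reference, moving) {
  fa <- stats::fft(reference)
  fb <- stats::fft(moving)
  cp <- fb * Conj(fa)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(stats::fft(cp / mag, inverse = TRUE))
  ij <- arrayInd(which.max(r), dim(r))
  dy <- ij[1] - 1L; dx <- ij[2] - 1L
  if (dy > nrow(r) / 2) dy <- dy - nrow(r)
  if (dx > ncol(r) / 2) dx <- dx - ncol(r)
  c(dx = dx, dy = dy)
}

## internal: circular integer shift of a matrix by (dx, dy)
.shiftFrame <- function(fr, dx, dy) {
  if (dx == 0 && dy == 0) return(fr)
  nr <- nrow(fr); nc <- ncol(fr)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  fr[ri, ci]
}

#' Translational stack registration by phase correlation
#'
#' Aligns every frame to frame 0 with the integer-pixel translation that
#' maximizes the phase correlation (rigid stage-drift correction; no
#' rotation or scaling). Shifts are reported per frame as the displacement
#' of the frame content relative to frame 0, and are undone by a circular
#' shift.
#'
#' @param stack a [Stack-class].
#' @return list with `stack` (registered [Stack-class]) and `shifts`
#'   (data frame: `frame` 0-based, `dx`, `dy` in pixels).
#' @export
registerStack <- function(stack) {
  stopifnot(is(stack, "Stack"))
  nT <- dim(stack@frames)[3]
  if (nT < 1) stop("stack has no frames")
  ref <- stack@frames[, , 1]
  shifts <- matrix(0L, nT, 2, dimnames = list(NULL, c("dx", "dy")))
  out <- stack@frames
  for (t in seq_len(nT)[-1]) {
    s <- .phaseShift(ref, stack@frames[, , t])
    shifts[t, ] <- s
    out[, , t] <- .shiftFrame(stack@frames[, , t], -s["dx"], -s["dy"])
  }
  list(stack = imageStack(out, dt = stack@dt, channel = stack@channel),
       shifts = data.frame(frame = seq_len(nT) - 1L,
                           dx = shifts[, "dx"], dy = shifts[, "dy"]))
}
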