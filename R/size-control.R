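#' @include AllClasses.R
NULL

#' Ellipsoid cell volume from axis lengths
#'
#' The default reproduces the volume formula as used for these
#' measurements, `V = (4/3) * L * S^2` for long axis `L` and short axis
#' `S`; `usePi = TRUE` gives the geometric ellipsoid volume from full
#' axis lengths, `(pi/6) * L * S^2`. Only the scale differs, so
#' regression slopes on log volume are identical in both modes.
#'
#' @param L long axis, micrometers (`L >= S >= 0`).
#' @param S short axis, micrometers.
#' @param usePi use the geometric `pi/6` prefactor.
#' @return volume, cubic micrometers.
#' @examples
#' ellipsoidVolume(4, 3)  # 48
#' @export
ellipsoidVolume <- function(L, S, usePi = FALSE) {
  if (any(L < 0) || any(S < 0)) stop("axis lengths must be non-negative")
  if (any(S > L)) stop("short axis must not exceed long axis")
  pref <- if (usePi) pi / 6 else 4 / 3
  pref * L * S^2
}

#' Relative G1 growth of a cell
#'
#' `ln(V_bud / V_birth)`: the log-fold volume growth between birth and
#' bud emergence. Under exponential growth this is proportional to the
#' G1 duration, and a perfect sizer (fixed volume at Start) makes it an
#' affine function of `ln(V_birth)` with slope -1.
#'
#' @param vBirth,vBud volumes at birth and bud emergence.
#' @return dimensionless log-ratio; negative values (shrinkage) are
#'   flagged with a warning.
#' @export
relativeG1Growth <- function(vBirth, vBud) {
  if (any(vBirth <= 0)) stop("birth volume must be positive")
  out <- log(vBud / vBirth)
  if (any(out < 0))
    warning(sum(out < 0), " record(s) show negative G1 growth")
  out
}

## internal: size records -> (x = ln V_birth, y = rel G1 growth)
.sizeXY <- function(records) {
  stopifnot(is.data.frame(records))
  haveAxes <- all(c("l_birth", "s_birth") %in% names(records))
  if (!"v_birth" %in% names(records)) {
    if (!haveAxes) stop("records need v_birth or birth axis lengths")
    records$v_birth <- ellipsoidVolume(records$l_birth, records$s_birth)
  }
  if (!"rel_g1" %in% names(records)) {
    if (!"v_bud" %in% names(records)) {
      if (!all(c("l_bud", "s_bud") %in% names(records)))
        stop("records need rel_g1, v_bud or budding axis lengths")
      records$v_bud <- ellipsoidVolume(records$l_bud, records$s_bud)
    }
    records$rel_g1 <- suppressWarnings(
      relativeG1Growth(records$v_birth, records$v_bud))
  }
  list(x = log(records$v_birth), y = records$rel_g1)
}

#' Regression of relative G1 growth on log birth volume
#'
#' OLS fit of `rel_g1 ~ ln(V_birth)`. The slope encodes the size-control
#' regime: -1 for a sizer, 0 for no size control (a timer under
#' exponential growth). Volumes and `rel_g1` are computed from axis
#' lengths when absent from the records.
#'
#' @param records size-record data frame (see [simulateSizeCohort()] or
#'   [readSizeRecords()]).
#' @return a [SizeControlFit-class].
#' @export
fitSizeControl <- function(records) {
  d <- .sizeXY(records)
  n <- length(d$x)
  if (n < 3) stop("need at least 3 records")
  if (stats::var(d$x) == 0) stop("no variance in log birth volume")
  fit <- stats::lm(d$y ~ d$x)
  cf <- summary(fit)$coefficients
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0   # response without variance
  new("SizeControlFit", slope = cf[2, 1], intercept = cf[1, 1],
      se = cf[2, 2], p = cf[2, 4], r2 = r2, n = n)
}

setMethod("show", "SizeControlFit", function(object) {
  cat(sprintf(
    "SizeControlFit: slope %.3f (se %.3f, p %.3g), intercept %.3f, r^2 %.3f, n = %d\n",
    object@slope, object@se, object@p, object@intercept, object@r2,
    object@n))
})

#' Compare size-control slopes between two cohorts
#'
#' Nested-model (extra-sum-of-squares) F-test: the reduced model shares
#' one slope across cohorts (separate intercepts), the full model has
#' separate slopes;
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n1 + n2 - 4))` with
#' `(1, n1 + n2 - 4)` degrees of freedom.
#'
#' @param recordsA,recordsB size-record data frames for the two cohorts.
#' @return a [SlopeComparison-class].
#' @export
compareSlopes <- function(recordsA, recordsB) {
  a <- .sizeXY(recordsA); b <- .sizeXY(recordsB)
  if (length(a$x) < 3 || length(b$x) < 3)
    stop("both cohorts need at least 3 records")
  if (stats::var(a$x) == 0 || stats::var(b$x) == 0)
    stop("no variance in log birth volume in one cohort")
  x <- c(a$x, b$x); y <- c(a$y, b$y)
  g <- factor(rep(c("A", "B"), c(length(a$x), length(b$x))))
  reduced <- stats::lm(y ~ x + g)
  full <- stats::lm(y ~ x * g)
  an <- stats::anova(reduced, full)
  Fstat <- an$F[2]; p <- an$`Pr(>F)`[2]
  if (!is.finite(Fstat) || Fstat < 0) { Fstat <- 0; p <- 1 }  # equal RSS
  new("SlopeComparison", statistic = Fstat,
      df = c(an$Df[2], an$Res.Df[2]), p = p)
}

setMethod("show", "SlopeComparison", function(object) {
  cat(sprintf("SlopeComparison: F(%d, %d) = %.4g, p = %.4g\n",
              object@df[1], object@df[2], object@statistic, object@p))
})
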