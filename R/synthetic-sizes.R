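#' @include AllClasses.R
NULL

#' Simulate a cohort of birth/budding cell sizes
#'
#' Two generating regimes for the relation between birth volume and the
#' relative growth in G1 (`ln(V_bud / V_birth)`):
#' \describe{
#'   \item{sizer}{cells commit to budding at a fixed Start volume
#'     `vStart` (times multiplicative log-normal noise):
#'     `V_bud = vStart * exp(eps)`. With zero noise the relative G1 growth
#'     is exactly `ln(vStart) - ln(V_birth)`, i.e. slope -1 against log
#'     birth volume.}
#'   \item{linear}{relative G1 growth is drawn directly as
#'     `intercept + slope * ln(V_birth) + eps`.}
#' }
#' Birth volumes are log-normal. Axis lengths are back-computed at a fixed
#' aspect ratio so that [ellipsoidVolume()] reproduces the volumes.
#'
#' @param n number of cells (at least 3).
#' @param lnVbirthMean,lnVbirthSd mean and s.d. of log birth volume
#'   (defaults: median birth volume ~30 cubic micrometers, CV ~30%).
#' @param vStart threshold volume at Start (sizer mode).
#' @param slope,intercept target regression (linear mode).
#' @param noiseSd s.d. of the noise on relative G1 growth.
#' @param mode `"sizer"` or `"linear"`.
#' @param seed integer seed.
#' @param aspect long/short axis ratio used to back-compute axis lengths.
#' @return data frame of size records: `cell_id`, axis lengths at birth
#'   and bud emergence (`l_birth`, `s_birth`, `l_bud`, `s_bud`, in
#'   micrometers), volumes `v_birth`, `v_bud` and `rel_g1`.
#' @examples
#' rec <- simulateSizeCohort(n = 50, noiseSd = 0, seed = 1)
#' fitSizeControl(rec)  # slope exactly -1
#' @export
simulateSizeCohort <- function(n = 200, lnVbirthMean = log(30),
                               lnVbirthSd = 0.3, vStart = 60,
                               slope = -1, intercept = log(60),
                               noiseSd = 0.05,
                               mode = c("sizer", "linear"), seed = 1,
                               aspect = 1.3) {
  mode <- match.arg(mode)
  if (n < 3) stop("need at least 3 cells")
  set.seed(seed)
  vBirth <- exp(stats::rnorm(n, lnVbirthMean, lnVbirthSd))
  eps <- stats::rnorm(n, 0, noiseSd)
  if (mode == "sizer") {
    vBud <- vStart * exp(eps)
  } else {
    relG1 <- intercept + slope * log(vBirth) + eps
    vBud <- vBirth * exp(relG1)
  }
  axes <- function(v) {
    s <- (v / ((4 / 3) * aspect))^(1 / 3)
    cbind(l = aspect * s, s = s)
  }
  ab <- axes(vBirth); au <- axes(vBud)
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
             l_birth = ab[, "l"], s_birth = ab[, "s"],
             l_bud = au[, "l"], s_bud = au[, "s"],
             v_birth = vBirth, v_bud = vBud,
             rel_g1 = log(vBud / vBirth))
}
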