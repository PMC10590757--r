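#' @include AllClasses.R
NULL

#' Cohort summary: median amplitude and period with bootstrap CIs
#'
#' Medians of the per-cell dominant amplitude and period, with 95%
#' percentile confidence intervals from a seeded bootstrap over cells.
#'
#' @param components data frame from [quantifyCohort()] (columns
#'   `amplitude_au2`, `period_min`), or a numeric vector of amplitudes.
#' @param group group label.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return one-row data frame: `group`, `n_cells`, `median_amplitude`,
#'   `amplitude_ci_lo/hi`, `median_period`, `period_ci_lo/hi`.
#' @export
cohortSummary <- function(components, group = "cohort", nBoot = 2000,
                          seed = 1, level = 0.95) {
  if (is.numeric(components))
    components <- data.frame(amplitude_au2 = components,
                             period_min = NA_real_)
  n <- nrow(components)
  if (n < 1) stop("need at least one cell")
  set.seed(seed)
  alpha <- (1 - level) / 2
  bootCI <- function(x) {
    if (all(is.na(x))) return(c(NA_real_, NA_real_))
    meds <- vapply(seq_len(nBoot), function(b)
      stats::median(x[sample.int(n, n, replace = TRUE)], na.rm = TRUE),
      numeric(1))
    stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
  }
  aCI <- bootCI(components$amplitude_au2)
  pCI <- bootCI(components$period_min)
  data.frame(group = group, n_cells = n,
             median_amplitude = stats::median(components$amplitude_au2),
             amplitude_ci_lo = aCI[1], amplitude_ci_hi = aCI[2],
             median_period = stats::median(components$period_min,
                                           na.rm = TRUE),
             period_ci_lo = pCI[1], period_ci_hi = pCI[2])
}

#' Pairwise Dunn's test with Holm adjustment
#'
#' Rank-based post-hoc comparison across groups on the pooled ranks, with
#' tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tied value groups.
#' Two-sided normal p-values are Holm step-down adjusted across all
#' pairs. When the pooled data are constant the variance term vanishes
#' and `z = 0`, `p = 1` is reported.
#'
#' @param groups named list of numeric vectors (at least two non-empty
#'   groups).
#' @return data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p`, `p_holm`.
#' @export
dunnHolmCompare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) > 0))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  g <- rep(names(groups), lengths(groups))
  rk <- rank(pooled)
  rbar <- tapply(rk, g, mean)
  ns <- lengths(groups)
  tie <- table(pooled)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - Tcorr
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    a <- pairs[1, c]; b <- pairs[2, c]
    denom <- v0 * (1 / ns[[a]] + 1 / ns[[b]])
    if (denom <= 0) { z[c] <- 0; p[c] <- 1; next }
    z[c] <- (rbar[[a]] - rbar[[b]]) / sqrt(denom)
    p[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_holm = stats::p.adjust(p, method = "holm"))
}
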