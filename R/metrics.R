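# Performance measures: observed coverage, divergence from the nominal
# level, and the binomial Monte-Carlo standard error.

#' Observed coverage
#'
#' @param covered Number of replications whose interval contained the
#'   true value.
#' @param reps Number of replications.
#' @return `covered / reps`, vectorized.
#' @export
coverage <- function(covered, reps) {
  if (any(reps < 1) || any(covered < 0) || any(covered > reps)) {
    stop("need 0 <= covered <= reps and reps >= 1", call. = FALSE)
  }
  covered / reps
}

#' Divergence from the nominal coverage level
#'
#' @param coverage Observed coverage proportion(s).
#' @param nominal Nominal level (default 0.95).
#' @return `abs(coverage - nominal)`, vectorized.
#' @export
divergence <- function(coverage, nominal = 0.95) abs(coverage - nominal)

#' Monte-Carlo standard error of an observed coverage
#'
#' @param coverage Observed coverage proportion(s).
#' @param reps Number of replications.
#' @return `sqrt(coverage * (1 - coverage) / reps)`, vectorized.
#' @export
mcse <- function(coverage, reps) sqrt(coverage * (1 - coverage) / reps)

#' Overall coverage pooled across scenarios
#'
#' Pools replications across all scenarios per estimator: overall
#' coverage is total covered over total replications (equal to the
#' unweighted mean of per-scenario coverages when `reps` is constant),
#' with divergence and MCSE computed from the pooled value.
#'
#' @param per_scenario Per-scenario results from [run_study()] (columns
#'   `method`, `covered`, `reps`).
#' @param nominal Nominal coverage level.
#' @return A data frame with one row per estimator: `method`, `reps`
#'   (pooled), `covered`, `coverage`, `divergence`, `mcse`, sorted by
#'   increasing divergence.
#' @export
summarize_overall <- function(per_scenario, nominal = 0.95) {
  stopifnot(all(c("method", "covered", "reps") %in% names(per_scenario)))
  agg <- stats::aggregate(cbind(covered, reps) ~ method,
                          data = per_scenario, FUN = sum)
  agg$coverage <- coverage(agg$covered, agg$reps)
  agg$divergence <- divergence(agg$coverage, nominal)
  agg$mcse <- mcse(agg$coverage, agg$reps)
  agg[order(agg$divergence), c("method", "reps", "covered", "coverage",
                               "divergence", "mcse")]
}
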