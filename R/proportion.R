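#' Sequence ratio point estimate
#'
#' The sequence ratio (SR) is the number of exposure-to-outcome sequences
#' divided by the number of outcome-to-exposure sequences; it estimates the
#' incidence rate ratio of the underlying cohort. Treating a sequence as a
#' Bernoulli trial with success "exposure before outcome", the SR is the
#' odds `x / (n - x)`.
#'
#' @param x Number of exposure-to-outcome sequences.
#' @param n Total number of sequences (`n >= 1`).
#'
#' @return `x / (n - x)`; `0` when `x = 0`, `Inf` when `x = n`. Vectorized
#'   over `x` and `n`.
#' @examples
#' sr_point(10, 15) # 2
#' @export
sr_point <- function(x, n) {
  if (any(n < 1) || any(x < 0) || any(x > n)) {
    stop("need 0 <= x <= n and n >= 1", call. = FALSE)
  }
  x / (n - x)
}

#' Binomial proportion compatibility interval
#'
#' Two-sided interval for a binomial proportion by one of the three
#' constructions used as building blocks for variance-summation ACSR
#' intervals: Clopper-Pearson (exact, beta quantiles), Jeffreys
#' (equal-tailed posterior under the Beta(1/2, 1/2) prior), or
#' Agresti-Coull (adjusted Wald).
#'
#' Boundary conventions: the lower limit is 0 when `x = 0` and the upper
#' limit is 1 when `x = n` for the two beta-based intervals; Agresti-Coull
#' limits are truncated to `[0, 1]`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Nominal coverage level in (0, 1).
#' @param method `"clopper_pearson"`, `"agresti_coull"`, or `"jeffreys"`.
#'
#' @return An [ci_interval()] on the proportion scale with estimate `x/n`.
#' @examples
#' binom_ci(5, 10, 0.95, "clopper_pearson")
#' @export
binom_ci <- function(x, n, level = 0.95,
                     method = c("clopper_pearson", "agresti_coull",
                                "jeffreys")) {
  method <- match.arg(method)
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop("need integer counts with 0 <= x <= n and n >= 1", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  al2 <- (1 - level) / 2
  bounds <- switch(method,
    clopper_pearson = c(
      if (x == 0) 0 else stats::qbeta(al2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - al2, x + 1, n - x)
    ),
    jeffreys = c(
      if (x == 0) 0 else stats::qbeta(al2, x + 0.5, n - x + 0.5),
      if (x == n) 1 else stats::qbeta(1 - al2, x + 0.5, n - x + 0.5)
    ),
    agresti_coull = {
      z <- stats::qnorm(1 - al2)
      nt <- n + z^2
      pt <- (x + z^2 / 2) / nt
      hw <- z * sqrt(pt * (1 - pt) / nt)
      c(max(0, pt - hw), min(1, pt + hw))
    }
  )
  ci_interval(bounds[1], bounds[2], level, scale = "proportion",
              estimate = x / n)
}

#' Map a proportion-scale interval to the sequence-ratio scale
#'
#' Applies the strictly increasing odds map `p -> p / (1 - p)` to both
#' limits; `p = 1` maps to `Inf` and `p = 0` to 0. This is the inverse of
#' the probability `p = SR / (1 + SR)` that generates sequence counts from
#' a true sequence ratio.
#'
#' @param ci An [ci_interval()] on the proportion scale.
#' @return An [ci_interval()] on the sequence-ratio scale.
#' @examples
#' sr_interval_from_proportion(binom_ci(5, 10, 0.95))
#' @export
sr_interval_from_proportion <- function(ci) {
  stopifnot(inherits(ci, "acsr_interval"))
  if (ci$scale != "proportion") {
    stop("interval must be on the proportion scale", call. = FALSE)
  }
  odds <- function(p) if (p >= 1) Inf else p / (1 - p)
  ci_interval(odds(ci$lower), odds(ci$upper), ci$level,
              scale = "sequence_ratio",
              estimate = if (is.na(ci$estimate)) NA_real_ else
                odds(ci$estimate))
}

#' Log-scale variance implied by an interval's limits
#'
#' Recovers the normal-theory variance of the log sequence ratio from the
#' limits of an interval: `((ln U - ln L) / (2 z))^2` with `z` the
#' `1 - alpha/2` standard-normal quantile. Returns `Inf` when the interval
#' touches 0 or `Inf`, the limit of the formula.
#'
#' @param ci An [ci_interval()] on the sequence-ratio (or ACSR) scale.
#' @param level Level whose `z` quantile converts the width; defaults to
#'   the interval's own level.
#' @return A non-negative number, possibly `Inf`.
#' @export
log_variance_from_interval <- function(ci, level = ci$level) {
  stopifnot(inherits(ci, "acsr_interval"))
  if (ci$lower <= 0 || !is.finite(ci$upper)) return(Inf)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ((log(ci$upper) - log(ci$lower)) / (2 * z))^2
}
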