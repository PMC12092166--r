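# Interval estimators for the active comparator sequence ratio (ACSR).
#
# The ACSR is the SR of the drug of interest divided by the SR of the
# comparator; on the 2x2 sequence table it is the odds ratio
# (a/b) / (c/d).  Six 95%-style constructions are provided: three
# variance-summation Wald intervals (on Clopper-Pearson, Agresti-Coull or
# Jeffreys per-drug intervals), the Woolf logit interval, the
# Baptista-Pike mid-p interval and the Miettinen-Nurminen score interval.
#
# All estimators are canonicalized in table orientation: a table and its
# row-transpose are mapped to a single orientation before computation and
# the limits of the other orientation are obtained by exact reciprocal
# inversion, so transposition antisymmetry (L, U) -> (1/U, 1/L) holds at
# the floating-point level.

# cap on |ln psi| beyond which a limit is declared 0 / Inf, and the
# absolute bisection tolerance on ln psi
.LNPSI_CAP <- 50
.LNPSI_TOL <- 1e-8

z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# TRUE when the transposed orientation (c, d, a, b) is lexicographically
# smaller than (a, b, c, d); ties (self-transposed tables) stay put.
transpose_first <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  y <- c(c, d, a, b)
  i <- which(x != y)
  length(i) > 0L && x[i[1]] > y[i[1]]
}

invert_limits <- function(r) {
  list(lower = 1 / r$upper, upper = 1 / r$lower, estimate = 1 / r$estimate)
}

# Run an estimator implementation on the canonical orientation of the
# table; `impl(a, b, c, d, level)` must return list(lower, upper, estimate).
canonical_acsr <- function(t, level, impl) {
  if (transpose_first(t$a, t$b, t$c, t$d)) {
    invert_limits(impl(t$c, t$d, t$a, t$b, level))
  } else {
    impl(t$a, t$b, t$c, t$d, level)
  }
}

acsr_point <- function(a, b, c, d) (a / b) / (c / d)

finish_interval <- function(r, level) {
  ci_interval(r$lower, r$upper, level, scale = "acsr", estimate = r$estimate)
}

## ---- variance-summation Wald intervals -----------------------------------

wald_sum_impl <- function(base) {
  function(a, b, c, d, level) {
    n1 <- a + b
    n2 <- c + d
    est <- acsr_point(a, b, c, d)
    v1 <- log_variance_from_interval(
      sr_interval_from_proportion(binom_ci(a, n1, level, base)), level)
    v2 <- log_variance_from_interval(
      sr_interval_from_proportion(binom_ci(c, n2, level, base)), level)
    if (!is.finite(v1) || !is.finite(v2) ||
        !is.finite(est) || est == 0) {
      return(list(lower = 0, upper = Inf, estimate = est))
    }
    z <- z_quantile(level)
    hw <- z * sqrt(v1 + v2)
    list(lower = exp(log(est) - hw), upper = exp(log(est) + hw),
         estimate = est)
  }
}

#' Variance-summation Wald interval for the ACSR
#'
#' The classical recommendation for active-comparator sequence ratios:
#' compute a proportion interval for each drug, transform it to the
#' sequence-ratio scale via `p / (1 - p)`, read off each drug's log-SR
#' variance from its interval width, sum the two variances and build a
#' normal-theory interval around the log ACSR. When either per-drug
#' interval touches the boundary (a zero count, a count equal to `n`, or
#' an Agresti-Coull limit truncated at 0 or 1) the implied variance is
#' infinite and the interval is the uninformative `(0, Inf)`.
#'
#' @param t A [sequence_table()] (or numeric `c(a, b, c, d)`).
#' @param level Nominal coverage level.
#' @param base Proportion interval used per drug: `"clopper_pearson"`,
#'   `"agresti_coull"` or `"jeffreys"`.
#' @return An [ci_interval()] on the ACSR scale.
#' @examples
#' acsr_wald_sum(sequence_table(10, 5, 5, 10), base = "agresti_coull")
#' @export
acsr_wald_sum <- function(t, level = 0.95,
                          base = c("clopper_pearson", "agresti_coull",
                                   "jeffreys")) {
  t <- as_sequence_table(t)
  base <- match.arg(base)
  finish_interval(canonical_acsr(t, level, wald_sum_impl(base)), level)
}

## ---- Woolf logit interval ------------------------------------------------

woolf_impl <- function(a, b, c, d, level) {
  if (min(a, b, c, d) == 0) {
    # Haldane-Anscombe correction: +0.5 on all four cells
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lest <- (log(a) + log(d)) - (log(b) + log(c))
  hw <- z_quantile(level) * sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(lower = exp(lest - hw), upper = exp(lest + hw), estimate = exp(lest))
}

#' Woolf logit interval for the ACSR
#'
#' Normal-theory interval on the log odds ratio of the 2x2 sequence table
#' with the delta-method variance `1/a + 1/b + 1/c + 1/d`. When any cell
#' is zero, the Haldane-Anscombe correction adds 0.5 to every cell for
#' both the point estimate and the variance, keeping the interval defined
#' on the full sample space.
#'
#' @inheritParams acsr_wald_sum
#' @return An [ci_interval()] on the ACSR scale.
#' @examples
#' woolf_logit_ci(sequence_table(10, 5, 5, 10))
#' @export
woolf_logit_ci <- function(t, level = 0.95) {
  t <- as_sequence_table(t)
  finish_interval(canonical_acsr(t, level, woolf_impl), level)
}

## ---- noncentral hypergeometric pmf ---------------------------------------

nchg_support <- function(n1, n2, m) {
  kmin <- max(0, m - n2)
  kmax <- min(n1, m)
  if (m < 0 || m > n1 + n2 || kmin > kmax) {
    stop("empty support: need 0 <= m <= n1 + n2", call. = FALSE)
  }
  kmin:kmax
}

# log pmf over the whole support for log odds ratio `lnpsi`
nchg_logpmf_support <- function(k, lc, lnpsi) {
  lp <- lc + k * lnpsi
  lp - logsumexp(lp)
}

#' Fisher's noncentral hypergeometric probability mass function
#'
#' Distribution of the first cell of a 2x2 table with fixed margins
#' (`n1`, `n2` row totals, `m` first-column total) and odds ratio `psi`:
#' `C(n1, k) C(n2, m - k) psi^k` normalized over the support
#' `max(0, m - n2) <= k <= min(n1, m)`. Computed in log space.
#'
#' @param k Cell count(s) at which to evaluate; values outside the
#'   support return 0.
#' @param n1,n2 Row totals.
#' @param m Conditioning column total.
#' @param psi Odds ratio, `psi > 0`.
#' @return Probabilities, vectorized over `k`.
#' @examples
#' nchg_pmf(0:5, 5, 5, 5, 1)  # central hypergeometric
#' @export
nchg_pmf <- function(k, n1, n2, m, psi) {
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 0) {
    stop("psi must be a single positive number", call. = FALSE)
  }
  ks <- nchg_support(n1, n2, m)
  lc <- lchoose(n1, ks) + lchoose(n2, m - ks)
  pmf <- exp(nchg_logpmf_support(ks, lc, log(psi)))
  out <- numeric(length(k))
  inside <- k %in% ks
  out[inside] <- pmf[match(k[inside], ks)]
  out
}

## ---- Baptista-Pike mid-p interval ----------------------------------------

# mid-p value of the conditional probability-based test at log psi:
# P(f(K) < f(a)) + P(f(K) = f(a)) / 2 under the noncentral hypergeometric.
# Ties in the pmf are detected in log space with relative tolerance 1e-12.
midp_value <- function(lnpsi, k, lc, ia) {
  lf <- nchg_logpmf_support(k, lc, lnpsi)
  lfa <- lf[ia]
  tol <- 1e-12 * max(1, abs(lfa))
  dif <- lf - lfa
  w <- exp(lf)
  sum(w[dif < -tol]) + 0.5 * sum(w[abs(dif) <= tol])
}

bp_midp_impl <- function(a, b, c, d, level) {
  n1 <- a + b
  n2 <- c + d
  m <- a + c
  est <- acsr_point(a, b, c, d)
  k <- nchg_support(n1, n2, m)
  if (length(k) == 1L) {
    return(list(lower = 0, upper = Inf, estimate = est))
  }
  lc <- lchoose(n1, k) + lchoose(n2, m - k)
  ia <- match(a, k)
  alpha <- 1 - level
  f <- function(x) midp_value(x, k, lc, ia)

  # anchor strictly inside the interval; the corrected odds ratio is an
  # interior point except in pathological cases caught by the grid scan
  ln0 <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
  if (f(ln0) < alpha) {
    grid <- seq(-.LNPSI_CAP, .LNPSI_CAP, length.out = 201)
    vals <- vapply(grid, f, numeric(1))
    if (max(vals) < alpha) {
      stop("mid-p function below alpha everywhere; table not invertible",
           call. = FALSE)
    }
    ln0 <- grid[which.max(vals)]
  }

  # The mid-p function is discontinuous where some support point's pmf
  # ties with the observed table's, and it is not monotone between
  # crossings either (it can dip below alpha and recover), so its
  # acceptance region may be non-contiguous. The reported interval is
  # the component containing the anchor as resolved on a fixed
  # logarithmic lattice augmented with the tie flanks — the same lattice
  # the grid-inversion oracle evaluates — scanned outward from the
  # anchor, with the limit refined by bisection inside the first lattice
  # cell whose far end falls below alpha.
  ties <- (lc[ia] - lc[k != a]) / (k[k != a] - a)
  lat <- bp_scan_lattice(ties)
  lower <- if (a == k[1]) 0 else
    exp(lattice_limit(f, ln0, alpha, lat, side = "lower"))
  upper <- if (a == k[length(k)]) Inf else
    exp(lattice_limit(f, ln0, alpha, lat, side = "upper"))
  list(lower = lower, upper = upper, estimate = est)
}

# ln-psi evaluation lattice shared (by construction) with the mid-p grid
# oracle: log-spaced points at step 0.035 on [-35, 35] plus both flanks
# of every pmf tie point
.LNPSI_GRID <- seq(-35, 35, length.out = 2001)
bp_scan_lattice <- function(ties) {
  ties <- ties[is.finite(ties) & abs(ties) < 35]
  sort(unique(c(.LNPSI_GRID, ties - 1e-6, ties, ties + 1e-6)))
}

# bisection between a point inside {f >= alpha} and one outside
bisect_pair <- function(f, inside, outside, alpha) {
  while (abs(outside - inside) > .LNPSI_TOL) {
    mid <- (outside + inside) / 2
    if (f(mid) >= alpha) inside <- mid else outside <- mid
  }
  (outside + inside) / 2
}

# Boundary of the lattice-resolved component of {x : f(x) >= alpha}
# containing the inside anchor x_in: walk outward over lattice points
# until f drops below alpha, then bisect within that cell. Returns
# +-Inf when the cap is reached with f still above alpha.
lattice_limit <- function(f, x_in, alpha, lat, side) {
  sgn <- if (side == "lower") -1 else 1
  pts <- lat[sgn * lat > sgn * x_in]
  if (length(pts)) {
    pts <- pts[order(sgn * pts)]
    for (x in pts) {
      if (f(x) < alpha) return(bisect_pair(f, x_in, x, alpha))
      x_in <- x
    }
  }
  cap <- sgn * .LNPSI_CAP
  if (f(cap) >= alpha) return(sgn * Inf)
  bisect_pair(f, x_in, cap, alpha)
}

#' Baptista-Pike mid-p interval for the ACSR
#'
#' Conditions on the total number of exposure-to-outcome sequences
#' `m = a + c`, under which the drug-of-interest count follows Fisher's
#' noncentral hypergeometric distribution with odds ratio `psi`, and
#' inverts the probability-based exact test with the mid-p correction:
#' the interval is the component of `{psi : midp(psi) >= alpha}`,
#' `alpha = 1 - level`, containing the point estimate, located by
#' bisection outward from it. The lower limit is 0 when `a` sits at the bottom
#' of the conditional support and the upper limit `Inf` when it sits at
#' the top; a degenerate support (`m = 0` or `m = n1 + n2`) yields
#' `(0, Inf)`.
#'
#' @inheritParams acsr_wald_sum
#' @return An [ci_interval()] on the ACSR scale.
#' @examples
#' bp_midp_ci(sequence_table(4, 1, 2, 3))
#' @export
bp_midp_ci <- function(t, level = 0.95) {
  t <- as_sequence_table(t)
  finish_interval(canonical_acsr(t, level, bp_midp_impl), level)
}

## ---- Miettinen-Nurminen score interval -----------------------------------

# Constrained MLE of the comparator proportion under odds ratio psi with
# margins fixed at the observed totals: root of the likelihood quadratic
#   A p2^2 + B p2 + C = 0,  A = n2 (psi - 1),
#   B = n1 psi + n2 - m (psi - 1),  C = -m.
# The admissible root (-B + sqrt(B^2 - 4AC)) / (2A) is evaluated in the
# algebraically equivalent form that avoids cancellation. Vectorized over
# psi.
mn_constrained_p2 <- function(psi, n1, n2, m) {
  A <- n2 * (psi - 1)
  B <- n1 * psi + n2 - m * (psi - 1)
  C0 <- -m
  # the discriminant is non-negative analytically but cancellation can
  # push it a hair below zero (e.g. psi -> 0 with m = n2)
  s <- sqrt(pmax(B * B - 4 * A * C0, 0))
  p2 <- ifelse(abs(A) < 1e-12 * n2, -C0 / B,
               ifelse(B > 0, -2 * C0 / (B + s), (-B + s) / (2 * A)))
  p2
}

# Miettinen-Nurminen score statistic as a function of ln psi (vectorized):
# difference of the two groups' standardized deviations from their
# constrained MLEs over the constrained-variance estimate with the
# N/(N-1) inflation; positive when the data favor a larger psi than the
# candidate. Constrained proportions are kept a hair inside (0, 1) so
# extreme bracketing evaluations stay finite with the correct sign.
mn_z_stat <- function(lnpsi, a, n1, c, n2) {
  psi <- exp(lnpsi)
  m <- a + c
  N <- n1 + n2
  eps <- 1e-12
  # each constrained proportion from its own quadratic (group roles
  # swapped, odds ratio inverted for group 1): deriving p1 from a
  # clipped p2 through the constraint loses all precision in the tails
  p2 <- pmin(pmax(mn_constrained_p2(psi, n1, n2, m), eps), 1 - eps)
  p1 <- pmin(pmax(mn_constrained_p2(1 / psi, n2, n1, m), eps), 1 - eps)
  t1 <- p1 * (1 - p1)
  t2 <- p2 * (1 - p2)
  num <- (a / n1 - p1) / t1 - (c / n2 - p2) / t2
  v <- (1 / (n1 * t1) + 1 / (n2 * t2)) * N / (N - 1)
  num / sqrt(v)
}

# Root of a decreasing function g on ln psi: geometric bracketing from x0
# then bisection; +-Inf when the cap is reached with no sign change.
root_decreasing <- function(g, x0) {
  cap <- .LNPSI_CAP
  g0 <- g(x0)
  if (is.na(g0)) stop("score statistic undefined at anchor", call. = FALSE)
  if (g0 >= 0) {
    lo <- x0
    step <- 1
    repeat {
      hi <- lo + step
      if (hi > cap) {
        if (g(cap) >= 0) return(Inf)
        hi <- cap
        break
      }
      if (g(hi) < 0) break
      lo <- hi
      step <- step * 2
    }
  } else {
    hi <- x0
    step <- 1
    repeat {
      lo <- hi - step
      if (lo < -cap) {
        if (g(-cap) < 0) return(-Inf)
        lo <- -cap
        break
      }
      if (g(lo) >= 0) break
      hi <- lo
      step <- step * 2
    }
  }
  while (hi - lo > .LNPSI_TOL) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

mn_score_impl <- function(a, b, c, d, level) {
  n1 <- a + b
  n2 <- c + d
  m <- a + c
  est <- acsr_point(a, b, c, d)
  if (m == 0 || m == n1 + n2) {
    return(list(lower = 0, upper = Inf, estimate = est))
  }
  zq <- z_quantile(level)
  ln0 <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
  lo <- root_decreasing(function(x) mn_z_stat(x, a, n1, c, n2) - zq, ln0)
  hi <- root_decreasing(function(x) mn_z_stat(x, a, n1, c, n2) + zq, ln0)
  list(lower = if (is.finite(lo)) exp(lo) else if (lo < 0) 0 else Inf,
       upper = if (is.finite(hi)) exp(hi) else if (hi > 0) Inf else 0,
       estimate = est)
}

#' Miettinen-Nurminen score interval for the ACSR
#'
#' Inverts the odds-ratio score test: for each candidate `psi` the two
#' proportions are re-estimated by constrained maximum likelihood subject
#' to `odds(p1) = psi * odds(p2)` (a closed-form quadratic root), and the
#' score statistic — the difference of the two groups' standardized
#' deviations from their constrained fits, with the Miettinen-Nurminen
#' `N/(N-1)` variance inflation — is compared with the normal quantile.
#' Limits are found by bisection on `ln psi`; zero cells need no
#' correction, the corresponding limit is 0 or `Inf` exactly when the
#' score equation has no finite root.
#'
#' @inheritParams acsr_wald_sum
#' @return An [ci_interval()] on the ACSR scale.
#' @examples
#' mn_score_ci(sequence_table(4, 1, 2, 3))
#' @export
mn_score_ci <- function(t, level = 0.95) {
  t <- as_sequence_table(t)
  finish_interval(canonical_acsr(t, level, mn_score_impl), level)
}

## ---- registry and batch front end ----------------------------------------

.estimator_impls <- list(
  mn_score     = mn_score_impl,
  bp_midp      = bp_midp_impl,
  woolf        = woolf_impl,
  cp_sum       = wald_sum_impl("clopper_pearson"),
  ac_sum       = wald_sum_impl("agresti_coull"),
  jeffreys_sum = wald_sum_impl("jeffreys")
)

#' Available ACSR interval estimators
#'
#' @return Character vector of estimator identifiers understood by
#'   [acsr_ci()] and the simulation engine.
#' @export
acsr_estimators <- function() names(.estimator_impls)

# single dispatch point used by acsr_ci and the memoized cache
acsr_ci_one <- function(method, a, b, c, d, level) {
  impl <- .estimator_impls[[method]]
  if (is.null(impl)) stop("unknown estimator: ", method, call. = FALSE)
  canonical_acsr(sequence_table(a, b, c, d), level, impl)
}

#' Compute ACSR compatibility intervals for a sequence table
#'
#' @param t A [sequence_table()] or numeric `c(a, b, c, d)`.
#' @param level Nominal coverage level.
#' @param methods Estimator identifiers (see [acsr_estimators()]) or
#'   `"all"`.
#' @return A data frame with one row per estimator: counts, `method`,
#'   `estimate`, `lower`, `upper`, `level`. The estimate is the sample
#'   ACSR `(a/b)/(c/d)` (Haldane-Anscombe corrected for `woolf` when a
#'   cell is zero).
#' @examples
#' acsr_ci(sequence_table(10, 5, 5, 10))
#' @export
acsr_ci <- function(t, level = 0.95, methods = "all") {
  t <- as_sequence_table(t)
  if (identical(methods, "all")) methods <- acsr_estimators()
  if (!all(methods %in% acsr_estimators())) {
    stop("unknown estimator in `methods`", call. = FALSE)
  }
  rows <- lapply(methods, function(m) {
    r <- acsr_ci_one(m, t$a, t$b, t$c, t$d, level)
    data.frame(a = t$a, b = t$b, c = t$c, d = t$d, method = m,
               estimate = r$estimate, lower = r$lower, upper = r$upper,
               level = level, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
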