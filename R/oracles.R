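# Brute-force reference implementations: dense-grid inversions of the
# mid-p and score tests (correctness references for the bisection code),
# and exact coverage by enumeration of the bivariate binomial sample
# space (a noise-free alternative to Monte-Carlo replication, feasible
# because a scenario has only (n+1)^2 distinct tables).

#' Dense-grid inversion oracle for the Baptista-Pike mid-p interval
#'
#' Evaluates the mid-p function by full support enumeration on a dense
#' log-spaced grid of odds-ratio values (augmented with the flanks of
#' every pmf tie point, where the mid-p function is discontinuous) and
#' reports, for each limit, the bracketing grid points of the acceptance
#' region where the mid-p value is at least `1 - level` — the contiguous
#' component containing the point estimate when the region is
#' non-contiguous. Correctness reference only, not optimized.
#'
#' @param t A [sequence_table()] or numeric `c(a, b, c, d)`.
#' @param level Nominal coverage level.
#' @param grid Positive odds-ratio grid, increasing (default 2001
#'   log-spaced points on `exp(seq(-35, 35))`).
#' @return A list with `lower_lo`, `lower_hi`, `upper_lo`, `upper_hi`
#'   (grid brackets; 0 / `Inf` at the grid ends) and `grid_resolution`.
#' @export
grid_invert_midp <- function(t, level = 0.95,
                             grid = exp(seq(-35, 35, length.out = 2001))) {
  t <- as_sequence_table(t)
  m <- t$a + t$c
  k <- nchg_support(t$n1, t$n2, m)
  if (length(k) == 1L) {
    return(list(lower_lo = 0, lower_hi = 0, upper_lo = Inf, upper_hi = Inf,
                grid_resolution = length(grid)))
  }
  lc <- lchoose(t$n1, k) + lchoose(t$n2, m - k)
  ia <- match(t$a, k)
  # augment the grid with both flanks of every pmf tie point: the
  # acceptance region may end in a sliver right before a tie, invisible
  # to any fixed-step grid
  ties <- (lc[ia] - lc[k != t$a]) / (k[k != t$a] - t$a)
  ties <- ties[is.finite(ties) & abs(ties) < max(abs(log(grid)))]
  lng <- sort(unique(c(log(grid), ties - 1e-6, ties, ties + 1e-6)))
  grid <- exp(lng)
  M <- outer(k, lng) + lc                   # support x grid log-weights
  cmx <- apply(M, 2, max)
  lse <- log(colSums(exp(sweep(M, 2, cmx)))) + cmx
  lf <- sweep(M, 2, lse)
  w <- exp(lf)
  lfa <- lf[ia, ]
  tol <- 1e-12 * pmax(1, abs(lfa))
  dif <- sweep(lf, 2, lfa)
  less <- sweep(dif, 2, -tol, "<")
  tie <- sweep(abs(dif), 2, tol, "<=")
  midp <- colSums(w * less) + 0.5 * colSums(w * tie)
  anchor <- log(((t$a + 0.5) * (t$d + 0.5)) / ((t$b + 0.5) * (t$c + 0.5)))
  bracket_region(midp >= (1 - level), grid, anchor = anchor)
}

#' Dense-grid inversion oracle for the Miettinen-Nurminen score interval
#'
#' Evaluates the squared score statistic on a dense log-spaced grid and
#' reports the brackets of the region where it does not exceed the
#' squared normal quantile.
#'
#' @inheritParams grid_invert_midp
#' @return Same structure as [grid_invert_midp()].
#' @export
grid_invert_score <- function(t, level = 0.95,
                              grid = exp(seq(-35, 35, length.out = 2001))) {
  t <- as_sequence_table(t)
  m <- t$a + t$c
  if (m == 0 || m == t$n1 + t$n2) {
    return(list(lower_lo = 0, lower_hi = 0, upper_lo = Inf, upper_hi = Inf,
                grid_resolution = length(grid)))
  }
  z <- mn_z_stat(log(grid), t$a, t$n1, t$c, t$n2)
  anchor <- log(((t$a + 0.5) * (t$d + 0.5)) / ((t$b + 0.5) * (t$c + 0.5)))
  bracket_region(z^2 <= z_quantile(level)^2, grid, anchor = anchor)
}

# Brackets of the acceptance region on an increasing grid: the lower
# limit lies in [lower_lo, lower_hi], the upper in [upper_lo, upper_hi];
# regions reaching a grid end are reported as touching 0 / Inf. When an
# anchor (log odds ratio) is given and the region is non-contiguous, the
# contiguous run containing (or nearest) the anchor is reported — the
# component the test-inversion estimators return.
bracket_region <- function(inside, grid, anchor = NULL) {
  if (!any(inside)) {
    stop("acceptance region missed by the grid; refine it", call. = FALSE)
  }
  idx <- which(inside)
  if (is.null(anchor)) {
    i1 <- idx[1]
    i2 <- idx[length(idx)]
  } else {
    j <- which.min(abs(log(grid) - anchor))
    if (!inside[j]) j <- idx[which.min(abs(idx - j))]
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    run <- runs[[which(vapply(runs, function(r) j %in% r, logical(1)))]]
    i1 <- run[1]
    i2 <- run[length(run)]
  }
  list(
    lower_lo = if (i1 == 1L) 0 else grid[i1 - 1L],
    lower_hi = if (i1 == 1L) 0 else grid[i1],
    upper_lo = if (i2 == length(grid)) Inf else grid[i2],
    upper_hi = if (i2 == length(grid)) Inf else grid[i2 + 1L],
    grid_resolution = length(grid)
  )
}

#' Exact coverage of an estimator in one scenario
#'
#' Computes coverage without Monte-Carlo error by summing the bivariate
#' binomial probability `P(a) P(c)` over every table whose interval
#' contains the true ACSR — the reps-to-infinity limit of
#' [run_scenario()]; the sample space has only `(n+1)^2` points.
#'
#' @inheritParams run_scenario
#' @return Named numeric vector of exact coverages, one per estimator.
#' @examples
#' exact_coverage(5, 1, 1, methods = "woolf")
#' @export
exact_coverage <- function(n, sr_drug, sr_comp, level = 0.95,
                           methods = acsr_estimators()) {
  p1 <- true_probability(sr_drug)
  p2 <- true_probability(sr_comp)
  acsr_true <- sr_drug / sr_comp
  w <- outer(stats::dbinom(0:n, n, p1), stats::dbinom(0:n, n, p2))
  vapply(methods, function(m) {
    bm <- bounds_matrices(m, n, level)
    sum(w[bm$lower <= acsr_true & acsr_true <= bm$upper])
  }, numeric(1))
}

#' Exact coverage over a scenario grid
#'
#' @param grid Scenario grid from [build_grid()].
#' @param level Nominal coverage level.
#' @param methods Estimator identifiers.
#' @return Per-scenario data frame: the grid columns plus `method`,
#'   `coverage` (exact) and `divergence`.
#' @export
exact_coverage_study <- function(grid = build_grid(), level = 0.95,
                                 methods = acsr_estimators()) {
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cov <- exact_coverage(g$n, g$sr_drug, g$sr_comp, level, methods)
    cbind(g[rep(1, length(cov)), , drop = FALSE],
          data.frame(method = names(cov), coverage = unname(cov)),
          row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$divergence <- divergence(out$coverage, level)
  out
}

#' Overall exact coverage pooled over scenarios
#'
#' With equal replication weight per scenario, pooled coverage is the
#' unweighted mean of per-scenario exact coverages.
#'
#' @param per_scenario Result of [exact_coverage_study()].
#' @param nominal Nominal coverage level.
#' @return One row per estimator: `method`, `coverage`, `divergence`,
#'   sorted by increasing divergence.
#' @export
summarize_exact_overall <- function(per_scenario, nominal = 0.95) {
  agg <- stats::aggregate(coverage ~ method, data = per_scenario,
                          FUN = mean)
  agg$divergence <- divergence(agg$coverage, nominal)
  agg[order(agg$divergence), ]
}
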