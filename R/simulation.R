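# Binomial simulation engine: scenario grid, per-scenario replicated
# draws, and a table-level memoization cache shared by the Monte-Carlo
# runner and the exact-coverage calculators. A scenario draws, per
# replication, the exposure-to-outcome count for each drug from
# Binomial(n, p) with p = SR_true / (1 + SR_true); every interval is a
# pure function of (a, b, c, d, level), so results are cached by table.

.acsr_cache <- new.env(parent = emptyenv())

#' Clear the memoized interval cache
#'
#' Interval limits are cached per (estimator, table, level). The cache is
#' transparent — it never changes results — but can be cleared to bound
#' memory or to time cold runs.
#' @return Invisibly, the number of entries removed.
#' @export
acsr_cache_clear <- function() {
  n <- length(ls(.acsr_cache))
  rm(list = ls(.acsr_cache), envir = .acsr_cache)
  invisible(n)
}

# memoized limits: numeric c(lower, upper)
cached_limits <- function(method, a, b, c, d, level) {
  key <- paste(method, a, b, c, d, level, sep = "|")
  val <- .acsr_cache[[key]]
  if (is.null(val)) {
    r <- acsr_ci_one(method, a, b, c, d, level)
    val <- c(r$lower, r$upper)
    assign(key, val, envir = .acsr_cache)
  }
  val
}

# lower/upper matrices over the full (a, c) sample space 0..n x 0..n for
# one estimator at equal per-drug totals n; rows index a, columns c.
bounds_matrices <- function(method, n, level) {
  lo <- matrix(NA_real_, n + 1, n + 1)
  hi <- matrix(NA_real_, n + 1, n + 1)
  for (a in 0:n) {
    for (cc in 0:n) {
      v <- cached_limits(method, a, n - a, cc, n - cc, level)
      lo[a + 1, cc + 1] <- v[1]
      hi[a + 1, cc + 1] <- v[2]
    }
  }
  list(lower = lo, upper = hi)
}

#' Binomial success probability implied by a true sequence ratio
#'
#' Under the generative model, the count of exposure-to-outcome sequences
#' among `n` observed sequences is Binomial(`n`, `p`) with
#' `p = SR_true / (1 + SR_true)`.
#'
#' @param sr_true True sequence ratio(s), positive.
#' @return `sr_true / (1 + sr_true)`, vectorized.
#' @examples
#' true_probability(c(0.5, 1, 2)) # 1/3, 1/2, 2/3
#' @export
true_probability <- function(sr_true) {
  if (any(sr_true <= 0)) stop("sr_true must be positive", call. = FALSE)
  sr_true / (1 + sr_true)
}

#' Build the simulation scenario grid
#'
#' One scenario per (number of sequences, unordered pair of true SRs with
#' repetition), canonicalized so the drug-of-interest SR is the larger of
#' the pair. The defaults — n from 5 to 50 and SRs in `{0.5, 1, 2}` —
#' give 46 x 6 = 276 scenarios.
#'
#' @param n_min,n_max Inclusive range of the per-drug number of sequences.
#' @param sr_values True sequence ratio values to combine.
#' @return A data frame with columns `scenario` (1-based grid index), `n`,
#'   `sr_drug`, `sr_comp` and `acsr_true = sr_drug / sr_comp`.
#' @examples
#' nrow(build_grid()) # 276
#' @export
build_grid <- function(n_min = 5, n_max = 50, sr_values = c(0.5, 1, 2)) {
  if (n_min > n_max || length(sr_values) == 0 || any(sr_values <= 0)) {
    stop("need n_min <= n_max and positive sr_values", call. = FALSE)
  }
  srs <- sort(unique(sr_values))
  pairs <- do.call(rbind, lapply(seq_along(srs), function(i) {
    data.frame(sr_drug = srs[i], sr_comp = srs[seq_len(i)])
  }))
  grid <- merge(data.frame(n = n_min:n_max), pairs, by = NULL)
  grid <- grid[order(grid$n, grid$sr_drug, grid$sr_comp), ]
  grid$acsr_true <- grid$sr_drug / grid$sr_comp
  grid <- data.frame(scenario = seq_len(nrow(grid)), grid,
                     row.names = NULL)
  grid
}

# deterministic per-scenario seed: order-independent streams derived from
# the master seed and the scenario's grid index (kept below 2^31)
scenario_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(index)) %%
               2147483647)
}

#' Run one simulation scenario
#'
#' Draws `reps` replications of the two binomial sequence counts and, for
#' each estimator, counts the replications whose interval contains the
#' true ACSR (`sr_drug / sr_comp`), using the closed interval
#' `[lower, upper]`.
#'
#' @param n Number of sequences per drug.
#' @param sr_drug,sr_comp True sequence ratios of the drug of interest and
#'   the comparator.
#' @param reps Number of replications.
#' @param level Nominal coverage level.
#' @param methods Estimator identifiers.
#' @param seed Optional integer seed set before drawing.
#' @param memoize Use the table-level interval cache (identical results,
#'   much faster; `FALSE` recomputes every replication, useful only to
#'   demonstrate cache transparency).
#' @return A data frame with columns `method`, `covered`, `reps`.
#' @examples
#' run_scenario(10, 2, 1, reps = 50, methods = "woolf", seed = 1)
#' @export
run_scenario <- function(n, sr_drug, sr_comp, reps = 5000, level = 0.95,
                         methods = acsr_estimators(), seed = NULL,
                         memoize = TRUE) {
  stopifnot(n >= 1, reps >= 1)
  if (!all(methods %in% acsr_estimators())) {
    stop("unknown estimator in `methods`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p1 <- true_probability(sr_drug)
  p2 <- true_probability(sr_comp)
  acsr_true <- sr_drug / sr_comp
  a <- stats::rbinom(reps, n, p1)
  cc <- stats::rbinom(reps, n, p2)
  covered <- vapply(methods, function(m) {
    if (memoize) {
      idx <- a * (n + 1) + cc + 1
      uniq <- sort(unique(idx))
      ua <- (uniq - 1) %/% (n + 1)
      uc <- (uniq - 1) %% (n + 1)
      cov_u <- vapply(seq_along(uniq), function(i) {
        v <- cached_limits(m, ua[i], n - ua[i], uc[i], n - uc[i], level)
        v[1] <= acsr_true && acsr_true <= v[2]
      }, logical(1))
      sum(cov_u[match(idx, uniq)])
    } else {
      sum(vapply(seq_len(reps), function(i) {
        r <- acsr_ci_one(m, a[i], n - a[i], cc[i], n - cc[i], level)
        r$lower <= acsr_true && acsr_true <= r$upper
      }, logical(1)))
    }
  }, numeric(1))
  data.frame(method = methods, covered = as.integer(covered), reps = reps,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a full Monte-Carlo coverage study
#'
#' Runs [run_scenario()] over a scenario grid with deterministic
#' per-scenario seeds derived from `master_seed`, so results do not
#' depend on execution order.
#'
#' @param grid Scenario grid from [build_grid()].
#' @param reps Replications per scenario.
#' @param level Nominal coverage level.
#' @param methods Estimator identifiers.
#' @param master_seed Integer master seed.
#' @return Per-scenario results: the grid columns plus `method`, `reps`,
#'   `covered`, `coverage`, `mcse` and `divergence` (from `level`).
#' @export
run_study <- function(grid = build_grid(), reps = 5000, level = 0.95,
                      methods = acsr_estimators(), master_seed = 20240501) {
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- run_scenario(g$n, g$sr_drug, g$sr_comp, reps = reps,
                        level = level, methods = methods,
                        seed = scenario_seed(master_seed, g$scenario))
    cbind(g[rep(1, nrow(res)), , drop = FALSE], res, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$coverage <- coverage(out$covered, out$reps)
  out$mcse <- mcse(out$coverage, out$reps)
  out$divergence <- divergence(out$coverage, level)
  out
}
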