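test_that("variance-summation Wald interval matches its compositional oracle", {
  # recompute the whole chain step by step with base R only
  z <- qnorm(0.975)
  a <- 10; b <- 5; cc <- 5; d <- 10
  n1 <- a + b; n2 <- cc + d
  nt <- n1 + z^2
  p1t <- (a + z^2 / 2) / nt
  hw1 <- z * sqrt(p1t * (1 - p1t) / nt)
  b1 <- c(p1t - hw1, p1t + hw1)
  p2t <- (cc + z^2 / 2) / nt
  hw2 <- z * sqrt(p2t * (1 - p2t) / nt)
  b2 <- c(p2t - hw2, p2t + hw2)
  odds <- function(p) p / (1 - p)
  v1 <- ((log(odds(b1[2])) - log(odds(b1[1]))) / (2 * z))^2
  v2 <- ((log(odds(b2[2])) - log(odds(b2[1]))) / (2 * z))^2
  est <- (a / b) / (cc / d)
  want <- exp(log(est) + c(-1, 1) * z * sqrt(v1 + v2))

  got <- acsr_wald_sum(sequence_table(a, b, cc, d), base = "agresti_coull")
  expect_equal(got$lower, want[1], tolerance = 1e-12)
  expect_equal(got$upper, want[2], tolerance = 1e-12)
  expect_equal(got$estimate, 4)
})

test_that("Wald-sum intervals collapse to (0, Inf) on boundary tables", {
  for (base in c("clopper_pearson", "agresti_coull", "jeffreys")) {
    r <- acsr_wald_sum(sequence_table(0, 5, 3, 4), base = base)
    expect_equal(r$lower, 0)
    expect_identical(r$upper, Inf)
  }
  r <- acsr_wald_sum(sequence_table(5, 0, 3, 4), base = "clopper_pearson")
  expect_equal(c(r$lower, r$upper), c(0, Inf))
})

test_that("identical drugs give intervals containing the null ACSR of 1", {
  t <- sequence_table(7, 4, 7, 4)
  for (m in acsr_estimators()) {
    r <- acsr_ci(t, methods = m)
    expect_lte(r$lower, 1)
    expect_gte(r$upper, 1)
  }
})

test_that("Woolf logit interval: closed form and zero-cell correction", {
  z <- qnorm(0.975)
  r <- woolf_logit_ci(sequence_table(5, 5, 5, 5))
  expect_equal(r$estimate, 1)
  expect_equal(r$lower, exp(-z * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(r$upper, exp(z * sqrt(0.8)), tolerance = 1e-12)

  expect_equal(woolf_logit_ci(sequence_table(10, 5, 5, 10))$estimate, 4)

  # any zero cell: all four cells get +0.5
  r0 <- woolf_logit_ci(sequence_table(0, 5, 5, 5))
  est <- (0.5 * 5.5) / (5.5 * 5.5)
  hw <- z * sqrt(1 / 0.5 + 3 / 5.5)
  expect_equal(r0$estimate, est, tolerance = 1e-12)
  expect_equal(r0$lower, est * exp(-hw), tolerance = 1e-12)
  expect_equal(r0$upper, est * exp(hw), tolerance = 1e-12)
})

test_that("noncentral hypergeometric pmf: central case, normalization, oracle", {
  # psi = 1 reduces to the central hypergeometric
  expect_equal(nchg_pmf(0:5, 5, 5, 5, 1), dhyper(0:5, 5, 5, 5),
               tolerance = 1e-12)
  # normalization over the support
  for (psi in c(0.1, 1, 10)) {
    expect_equal(sum(nchg_pmf(0:7, 4, 6, 7, psi)), 1, tolerance = 1e-12)
  }
  # direct enumeration oracle at n1 = n2 = 5, m = 5, psi = 2, k = 3
  wts <- choose(5, 0:5) * choose(5, 5 - (0:5)) * 2^(0:5)
  expect_equal(nchg_pmf(3, 5, 5, 5, 2), wts[4] / sum(wts), tolerance = 1e-12)
  # out-of-support k has zero mass; empty support errors
  expect_equal(nchg_pmf(6, 5, 5, 5, 2), 0)
  expect_error(nchg_pmf(0, 5, 5, 12, 1))
})

test_that("mid-p and score intervals agree with their grid-inversion oracles", {
  t <- sequence_table(4, 1, 2, 3)
  bp <- bp_midp_ci(t)
  ob <- grid_invert_midp(t)
  expect_gte(bp$lower, ob$lower_lo * (1 - 1e-9))
  expect_lte(bp$lower, ob$lower_hi * (1 + 1e-9))
  expect_gte(bp$upper, ob$upper_lo * (1 - 1e-9))
  expect_lte(bp$upper, ob$upper_hi * (1 + 1e-9))

  mn <- mn_score_ci(t)
  om <- grid_invert_score(t)
  expect_gte(mn$lower, om$lower_lo * (1 - 1e-9))
  expect_lte(mn$lower, om$lower_hi * (1 + 1e-9))
  expect_gte(mn$upper, om$upper_lo * (1 - 1e-9))
  expect_lte(mn$upper, om$upper_hi * (1 + 1e-9))
})

test_that("test-inversion intervals are log-symmetric on symmetric tables", {
  for (f in list(bp_midp_ci, mn_score_ci)) {
    r <- f(sequence_table(5, 5, 5, 5))
    expect_lte(r$lower, 1)
    expect_gte(r$upper, 1)
    expect_equal(log(r$lower) + log(r$upper), 0, tolerance = 1e-6)
  }
})

test_that("boundary counts put test-inversion limits at 0 or Inf", {
  # a at the top of the conditional support
  expect_identical(bp_midp_ci(sequence_table(5, 0, 1, 4))$upper, Inf)
  # degenerate margin m = 0
  r <- bp_midp_ci(sequence_table(0, 5, 0, 5))
  expect_equal(c(r$lower, r$upper), c(0, Inf))
  # zero cells for the score interval, no correction needed
  expect_equal(mn_score_ci(sequence_table(0, 5, 2, 3))$lower, 0)
  expect_identical(mn_score_ci(sequence_table(3, 2, 0, 5))$upper, Inf)
})

test_that("interval estimates sit inside their intervals on interior tables", {
  set.seed(11)
  tabs <- random_interior_tables(40)
  for (i in seq_len(nrow(tabs))) {
    t <- sequence_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    est <- (t$a / t$b) / (t$c / t$d)
    for (m in acsr_estimators()) {
      r <- acsr_ci(t, methods = m)
      expect_lte(r$lower, est * (1 + 1e-9))
      expect_gte(r$upper, est * (1 - 1e-9))
    }
  }
})

test_that("higher nominal levels give nested intervals", {
  set.seed(7)
  tabs <- random_tables(25)
  for (i in seq_len(nrow(tabs))) {
    t <- sequence_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    for (m in acsr_estimators()) {
      r90 <- acsr_ci(t, level = 0.90, methods = m)
      r95 <- acsr_ci(t, level = 0.95, methods = m)
      r99 <- acsr_ci(t, level = 0.99, methods = m)
      expect_lte(r99$lower, r95$lower + 1e-12)
      expect_lte(r95$lower, r90$lower + 1e-12)
      expect_gte(r99$upper, r95$upper * (1 - 1e-12))
      expect_gte(r95$upper, r90$upper * (1 - 1e-12))
    }
  }
})

test_that("batch front end validates input and returns one row per method", {
  out <- acsr_ci(sequence_table(4, 1, 2, 3))
  expect_equal(nrow(out), length(acsr_estimators()))
  expect_setequal(out$method, acsr_estimators())
  expect_true(all(out$lower <= out$upper))
  expect_error(acsr_ci(sequence_table(1, 1, 1, 1), methods = "fisher"))
  expect_error(sequence_table(-1, 2, 3, 4))
  expect_error(sequence_table(0, 0, 3, 4))
})
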