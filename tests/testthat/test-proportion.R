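test_that("sequence ratio point estimate handles interior and boundary counts", {
  expect_equal(sr_point(10, 15), 2)
  expect_equal(sr_point(0, 5), 0)
  expect_equal(sr_point(5, 10), 1)
  expect_equal(sr_point(5, 5), Inf)
  expect_error(sr_point(6, 5))
  expect_error(sr_point(1, 0))
})

test_that("Clopper-Pearson limits match a beta-CDF bisection oracle", {
  cases <- list(c(5, 10), c(1, 7), c(3, 20), c(11, 12))
  for (cs in cases) {
    x <- cs[1]
    n <- cs[2]
    ci <- binom_ci(x, n, 0.95, "clopper_pearson")
    expect_equal(ci$lower, qbeta_bisect(0.025, x, n - x + 1), tolerance = 1e-9)
    expect_equal(ci$upper, qbeta_bisect(0.975, x + 1, n - x), tolerance = 1e-9)
    cj <- binom_ci(x, n, 0.95, "jeffreys")
    expect_equal(cj$lower, qbeta_bisect(0.025, x + 0.5, n - x + 0.5),
                 tolerance = 1e-9)
    expect_equal(cj$upper, qbeta_bisect(0.975, x + 0.5, n - x + 0.5),
                 tolerance = 1e-9)
  }
})

test_that("proportion intervals respect boundary and symmetry conventions", {
  expect_equal(binom_ci(0, 5, 0.95, "clopper_pearson")$lower, 0)
  expect_equal(binom_ci(5, 5, 0.95, "clopper_pearson")$upper, 1)
  expect_equal(binom_ci(0, 5, 0.95, "jeffreys")$lower, 0)
  expect_equal(binom_ci(5, 5, 0.95, "jeffreys")$upper, 1)
  # x = n - x: interval symmetric about 1/2
  ci <- binom_ci(5, 10, 0.95, "clopper_pearson")
  expect_equal(ci$lower, 1 - ci$upper, tolerance = 1e-12)
  # Agresti-Coull recentering: adjusted center, truncation at 0
  ac0 <- binom_ci(0, 10, 0.95, "agresti_coull")
  expect_equal(ac0$lower, 0)
  expect_gt(ac0$upper, 0)
  expect_error(binom_ci(5, 4))
  expect_error(binom_ci(2, 5, level = 1.2))
})

test_that("Clopper-Pearson is never narrower than Jeffreys for interior x", {
  for (n in c(5, 10, 25)) {
    for (x in 1:(n - 1)) {
      cp <- binom_ci(x, n, 0.95, "clopper_pearson")
      jf <- binom_ci(x, n, 0.95, "jeffreys")
      expect_lte(cp$lower, jf$lower + 1e-12)
      expect_gte(cp$upper, jf$upper - 1e-12)
    }
  }
})

test_that("proportion-to-SR map applies the odds transform with boundaries", {
  ci <- ci_interval(1 / 3, 2 / 3, 0.95, "proportion")
  sr <- sr_interval_from_proportion(ci)
  expect_equal(sr$lower, 0.5)
  expect_equal(sr$upper, 2)
  deg <- sr_interval_from_proportion(ci_interval(0.5, 0.5, 0.95, "proportion"))
  expect_equal(deg$lower, 1)
  expect_equal(deg$upper, 1)
  top <- sr_interval_from_proportion(ci_interval(0.2, 1, 0.95, "proportion"))
  expect_identical(top$upper, Inf)
  expect_equal(sr_interval_from_proportion(
    ci_interval(0, 0.5, 0.95, "proportion"))$lower, 0)
})

test_that("log-variance recovered from interval limits", {
  z <- qnorm(0.975)
  expect_equal(log_variance_from_interval(
    ci_interval(1, 1, 0.95, "sequence_ratio")), 0)
  expect_equal(log_variance_from_interval(
    ci_interval(exp(-z), exp(z), 0.95, "sequence_ratio")), 1,
    tolerance = 1e-12)
  expect_identical(log_variance_from_interval(
    ci_interval(0, 4, 0.95, "sequence_ratio")), Inf)
  expect_identical(log_variance_from_interval(
    ci_interval(0.5, Inf, 0.95, "sequence_ratio")), Inf)
})
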