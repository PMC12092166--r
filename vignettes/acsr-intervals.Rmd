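---
title: "Interval estimators for active comparator sequence ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimators for active comparator sequence ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsrci)
```

## The estimation problem

Sequence symmetry analysis (SSA) is a self-controlled pharmacoepidemiologic
design: among patients who received both a drug and a marker of an outcome
(often a second drug), it compares how many started the drug of interest
*before* the outcome against how many started it *after*. The sequence ratio
(SR) — exposure-to-outcome sequences divided by outcome-to-exposure
sequences — estimates the incidence rate ratio of the underlying cohort and
is robust to time-invariant confounding, but not to time-varying
confounding such as confounding by indication. Dividing the SR of the drug
of interest by the SR of an *active comparator* (a drug with the same
indication) cancels shared time trends; the resulting active comparator
sequence ratio (ACSR) is the effect measure this package targets.

Writing `a`/`b` for the two sequence counts of the drug of interest and
`c`/`d` for the comparator, each drug's SR is a binomial odds
(`SR = x/(n-x)` with `n = x + (n-x)` observed sequences), and the ACSR

\[ \mathrm{ACSR} = \frac{a/b}{c/d} \]

is exactly the odds ratio of a 2×2 table with independent binomial rows.
All interval theory for the two-sample odds ratio therefore applies, and
the package implements the six constructions whose small-sample coverage
the simulation machinery evaluates:

* **Variance-summation Wald intervals** (`acsr_wald_sum()`, ids `cp_sum`,
  `ac_sum`, `jeffreys_sum`): the classical recommendation for
  active-comparator SSA. Each drug gets a binomial proportion interval
  (Clopper–Pearson, Agresti–Coull, or the equal-tailed Jeffreys
  posterior), mapped to the SR scale by the odds transform
  `p ↦ p/(1-p)`; each drug's log-SR variance is recovered from its
  interval width as `((ln U - ln L)/(2z))²`; the two variances are summed
  and a normal-theory interval is built around the sample log-ACSR.
* **Woolf logit** (`woolf_logit_ci()`): the delta-method interval on the
  log odds ratio with variance `1/a + 1/b + 1/c + 1/d`.
* **Baptista–Pike mid-p** (`bp_midp_ci()`): conditions on the margin
  `m = a + c`, under which `a` follows Fisher's noncentral hypergeometric
  law with odds ratio ψ, and inverts the probability-based exact test
  with the mid-p correction.
* **Miettinen–Nurminen score** (`mn_score_ci()`): inverts the
  unconditional score test. For each candidate ψ the two proportions are
  refitted by constrained maximum likelihood (a closed-form quadratic
  root), and the statistic is the difference of the two groups'
  standardized deviations from their constrained fits,
  \[(\hat p_1-\tilde p_1)/(\tilde p_1\tilde q_1)-(\hat p_2-\tilde
  p_2)/(\tilde p_2\tilde q_2),\] studentized by
  `sqrt((1/(n1 p̃1 q̃1) + 1/(n2 p̃2 q̃2)) · N/(N-1))`. The `N/(N-1)`
  inflation is part of the Miettinen–Nurminen construction. Both groups
  must appear in the numerator: a one-group variant degenerates as
  ψ → 0 whenever the conditioning margin exceeds the comparator's
  capacity, producing spurious zero lower limits.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `level` | 0.95 | nominal two-sided coverage; `z` is always the exact `1-α/2` normal quantile (≈ 1.959964), not a rounded 1.96, so any level works |
| `n_min`, `n_max` | 5, 50 | per-drug sequence counts in the scenario grid (inclusive integers: 46 values) |
| `sr_values` | 0.5, 1, 2 | true per-drug SRs; unordered pairs with repetition give 6 combinations, hence 276 scenarios |
| `reps` | 5000 | Monte-Carlo replications per scenario |
| `master_seed` | 20240501 | seed of the per-scenario streams |

## Numerical design

**Boundary tables.** Zero counts are common at these sample sizes
(at `n = 5` and SR = 1, each drug hits a boundary with probability
2·(1/2)⁵ ≈ 6%), so every estimator is total: no replication is ever
discarded.

* Variance-summation methods: when a per-drug proportion interval touches
  0 or 1 (a zero count for the beta-based intervals, or an Agresti–Coull
  limit truncated into `[0,1]`), the implied log variance is infinite —
  the limit of the width formula — and the ACSR interval is the
  uninformative `(0, ∞)`, which always covers. The same applies when the
  sample ACSR itself is 0, ∞ or undefined.
* Woolf: the Haldane–Anscombe correction (+0.5 on all four cells, for
  both the point estimate and the variance) whenever any cell is zero —
  the standard companion of the Woolf interval.
* Jeffreys: the equal-tailed posterior interval with the conventional
  boundary modification (lower limit 0 at `x = 0`, upper limit 1 at
  `x = n`), so the posterior interval never spuriously excludes a
  boundary the data sit on.
* Mid-p and score intervals need no correction: a limit is 0 or ∞
  exactly when the observed count sits at the end of the conditional
  support (mid-p) or the score equation has no finite root.

**Test inversion.** Both inversion intervals bisect on ln ψ with absolute
tolerance 1e-8, starting from the Haldane-corrected sample odds ratio
(always finite, always interior in practice; a coarse scan guards the
mid-p anchor) and expanding the bracket geometrically until the test
statistic crosses its critical value. Beyond |ln ψ| = 50 a limit is
declared 0 or ∞; at the grid's sample sizes true finite limits are orders
of magnitude inside that cap. Mid-p ties — probability-mass equality with
the observed table — are detected in log space with relative tolerance
1e-12, so symmetric tables get their half-weight deterministically.

The mid-p function needs extra care: it is discontinuous at pmf tie
points, it is not monotone between them (within a fixed comparison set
it is a sum of opposing monotone terms and can dip below α and recover),
and its acceptance region can be non-contiguous on boundary-heavy
tables. The reported interval is therefore defined operationally: the
acceptance component containing the anchor as resolved on a fixed
logarithmic lattice (step 0.035 over |ln ψ| ≤ 35, augmented with the
flanks of every tie point), scanned outward from the anchor, with the
limit refined by bisection inside the first lattice cell that falls
below α. The grid oracle evaluates the same lattice, so the two agree by
construction up to one lattice cell; features of the mid-p function
narrower than the lattice step are deliberately ignored by both. The
score statistic needs none of this — its acceptance region is a single
interval on every table the oracles sweep.

**Orientation canonicalization.** Transposing the drug rows maps the ACSR
to its reciprocal, and every estimator here is antisymmetric under that
map. Floating-point `exp`/`log`/division are not exactly involutive, so
each estimator computes on a canonical orientation of the table (the
lexicographically smaller of table and transpose) and returns exactly
reciprocal limits for the other orientation. For self-transposed tables
(`a = c`, `b = d`) the two limits come from independent bisections and are
reciprocal only to the root-finding tolerance.

**Memoization.** Every interval is a pure function of
`(a, b, c, d, level)`, and a scenario draws from at most `(n+1)²` distinct
tables, so the simulation engine caches limits per table in a
package-level environment (`acsr_cache_clear()` resets it). Memoized and
direct runs produce identical covered counts; the cache is shared across
scenarios and between the Monte-Carlo and exact engines.

## The generative model, and what it leaves out

`run_scenario()` draws, per replication, the exposure-to-outcome count of
each drug independently from `Binomial(n, p)` with `p = SR/(1+SR)`, both
drugs observing the same number of sequences `n` — the only reading under
which the published grid arithmetic (46 × 6 = 276 scenarios) is
consistent. Coverage counts the true ACSR inside the closed interval
`[lower, upper]`, so half-infinite intervals are handled uniformly.

This emulates the *statistical* content of an active-comparator SSA and
nothing else: there are no person-level prescription timelines, no
waiting-time or run-in truncation, no secular prescribing trends, no
dependence between the two drugs' sequence counts, and no
null-effect-SR adjustment. Passing coverage results therefore validate
the interval constructions under the binomial mechanism; they say nothing
about bias from the epidemiologic threats the design itself must manage.

Per-scenario seeds are derived arithmetically from
`(master_seed, scenario index)` and feed R's Mersenne–Twister, so results
are reproducible and independent of execution order; the generator
algorithm is fixed by the R version.

## Exact coverage as the primary instrument

Because the sample space of a scenario has at most 51² = 2601 points,
coverage can be computed *exactly* by summing the bivariate binomial mass
over covering tables (`exact_coverage()`,`exact_coverage_study()`). This
is the reps → ∞ limit of the Monte-Carlo design and is used as the
primary evaluation instrument: it is deterministic, strictly stronger
than replication at this problem size, and the Monte-Carlo engine is
retained to mirror the replication-based procedure and its MCSE
reporting. The test suite checks the two engines against each other
(Monte-Carlo coverage within 4 MCSE of the exact value).

The overall summary pools replications across scenarios — with equal
`reps` this is the unweighted mean of per-scenario coverages, and the
overall divergence is computed from the pooled coverage; per-scenario
divergences are also emitted so the alternative summary (mean absolute
per-scenario divergence) is computable from the same output.

## Problem sizes used by the shipped tests

The test suite runs the full 276-scenario exact study (about 45,000
distinct tables across the 46 sample sizes, six estimators each, a few
minutes with the memoized cache), validates the two inversion estimators
against dense-grid oracles on every table with per-drug totals up to 12
(8100 tables, 2001-point log grids spanning `ln ψ ∈ [-35, 35]`), checks
transposition antisymmetry on 1000 random tables, and reruns the
Monte-Carlo engine at 500 replications per scenario for the scaled-down
comparison. The oracle grids are references, not implementations: the
fast estimators must land inside the oracle's one-grid-step brackets.

## Known limitations

* The Wald-sum methods' `(0, ∞)` convention at boundary tables always
  covers, which *raises* their small-sample coverage; any convention that
  keeps those intervals finite changes coverage at `n ≲ 10` appreciably.
  Sensitivity to this choice is easy to probe by editing the boundary
  branch of `acsr_wald_sum()`; the shipped convention is the limit of the
  stated variance formula.
* The score and mid-p inversions assume the acceptance region is an
  interval in ψ; this holds for the implemented statistics on all tables
  the oracles sweep, but is asserted, not proved, for arbitrary inputs.
* `nchg_pmf()` enumerates the conditional support, which is fine for
  SSA-sized tables (hundreds of sequences) but not for margins in the
  tens of thousands.
* Exact coverage enumerates `(n+1)²` tables per scenario and is meant for
  grids of the published magnitude, not for `n` in the thousands.
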