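# Random valid sequence tables (counts 0..cmax, each drug with at least
# one sequence), built programmatically under the caller's RNG state.
random_tables <- function(n_tables, cmax = 12) {
  draw <- function() {
    repeat {
      x <- sample(0:cmax, 4, replace = TRUE)
      if (x[1] + x[2] >= 1 && x[3] + x[4] >= 1) return(x)
    }
  }
  t(vapply(seq_len(n_tables), function(i) draw(), integer(4)))
}

# Interior tables: all four cells positive.
random_interior_tables <- function(n_tables, cmax = 12) {
  t(vapply(seq_len(n_tables), function(i) {
    sample(1:cmax, 4, replace = TRUE)
  }, integer(4)))
}

# beta quantile by direct CDF bisection — independent of qbeta
qbeta_bisect <- function(p, shape1, shape2) {
  lo <- 0
  hi <- 1
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (stats::pbeta(mid, shape1, shape2) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
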