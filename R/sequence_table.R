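#' Observed sequence counts for a drug of interest and an active comparator
#'
#' A `sequence_table` holds the four counts of a sequence symmetry analysis
#' with an active comparator: for each drug, the number of
#' exposure-to-outcome sequences and the number of outcome-to-exposure
#' sequences. Algebraically the table is a 2x2 contingency table and the
#' active comparator sequence ratio (ACSR) is its odds ratio.
#'
#' @param a Exposure-to-outcome sequence count for the drug of interest.
#' @param b Outcome-to-exposure sequence count for the drug of interest.
#' @param c Exposure-to-outcome sequence count for the comparator drug.
#' @param d Outcome-to-exposure sequence count for the comparator drug.
#'
#' @return An object of class `sequence_table`: a list with elements
#'   `a`, `b`, `c`, `d` and the derived totals `n1 = a + b` (drug of
#'   interest) and `n2 = c + d` (comparator).
#'
#' @examples
#' sequence_table(10, 5, 5, 10)
#' @export
sequence_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4L || anyNA(counts) || !is.numeric(counts)) {
    stop("a, b, c, d must be four non-missing numeric counts", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("sequence counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  n1 <- counts[["a"]] + counts[["b"]]
  n2 <- counts[["c"]] + counts[["d"]]
  if (n1 < 1L || n2 < 1L) {
    stop("each drug needs at least one observed sequence (n1 >= 1, n2 >= 1)",
         call. = FALSE)
  }
  structure(
    list(a = counts[["a"]], b = counts[["b"]],
         c = counts[["c"]], d = counts[["d"]],
         n1 = n1, n2 = n2),
    class = "sequence_table"
  )
}

#' @export
print.sequence_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("drug of interest", "comparator"),
                              c("expo->outc", "outc->expo")))
  cat("Sequence table (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  print(m)
  invisible(x)
}

# Coerce a sequence_table or a length-4 count vector (a, b, c, d).
as_sequence_table <- function(x) {
  if (inherits(x, "sequence_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(sequence_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  stop("expected a sequence_table or a numeric vector c(a, b, c, d)",
       call. = FALSE)
}

# Swap the drug-of-interest and comparator rows.
transpose_table <- function(t) sequence_table(t$c, t$d, t$a, t$b)

#' Ratio-scale interval container
#'
#' Lightweight container for a two-sided interval with its nominal level
#' and the scale it lives on: a binomial proportion, a single-drug
#' sequence ratio, or an active comparator sequence ratio.
#'
#' @param lower Lower limit (0 allowed; must be in `[0, 1]` on the
#'   proportion scale).
#' @param upper Upper limit (`Inf` allowed off the proportion scale).
#' @param level Nominal coverage level in (0, 1).
#' @param scale One of `"proportion"`, `"sequence_ratio"`, `"acsr"`.
#' @param estimate Optional point estimate carried along for printing.
#'
#' @return An object of class `acsr_interval`.
#' @export
ci_interval <- function(lower, upper, level, scale = "acsr",
                        estimate = NA_real_) {
  scale <- match.arg(scale, c("proportion", "sequence_ratio", "acsr"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  if (is.na(lower) || is.na(upper) || lower > upper || lower < 0) {
    stop("need 0 <= lower <= upper", call. = FALSE)
  }
  if (scale == "proportion" && upper > 1) {
    stop("proportion-scale limits must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         level = level, scale = scale, estimate = as.numeric(estimate)),
    class = "acsr_interval"
  )
}

#' @export
print.acsr_interval <- function(x, ...) {
  cat(sprintf("%.0f%% interval on %s scale: [%g, %g]",
              100 * x$level, x$scale, x$lower, x$upper))
  if (!is.na(x$estimate)) cat(sprintf("  (estimate %g)", x$estimate))
  cat("\n")
  invisible(x)
}
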