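#' Round half away from zero
#'
#' Display rounding used in the summary tables: exact halves round up (2.285
#' -> 2.29 at two decimals), unlike [base::round()]'s banker's rounding. All
#' internal comparisons and sorting use unrounded values; this is applied only
#' when formatting output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a private RNG stream, restoring the caller's state afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' computed from the contingency table in closed form. Used to score recovery
#' of planted co-prescription communities by the clustering methods.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor), same
#'   length. Names are ignored; elements are matched by position.
#' @return a single number in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
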