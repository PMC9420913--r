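#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own seed stream so
#' that adding a stage (or re-ordering stages) never perturbs the draws of an
#' earlier one.  The sub-seed is a deterministic hash of the master seed and a
#' stage tag, kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param tag character stage tag, e.g. `"counts"` or `"mnn"`.
#' @return a single integer seed.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(as.integer(charToRaw(tag)) * seq_along(charToRaw(tag)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Uppercase gene symbols
#'
#' Gene symbols are uppercased before any matching: pig and human symbol
#' case conventions differ, and the whole pipeline matches by exact
#' case-insensitive symbol equality.
#'
#' @param x character vector of symbols.
#' @return uppercased character vector.
#' @export
upper_symbols <- function(x) toupper(trimws(as.character(x)))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index, a single number \eqn{\le 1}.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# stop() with a consistent prefix for user-facing validation errors
abort_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
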