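# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's global RNG
#' state afterwards, so seeded package functions never clobber user
#' randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the closed-form pair-counting expression on the
#' contingency table. Used by the recovery experiments to compare detected
#' modules with planted subgroup labels.
#'
#' @param a,b Vectors of labels of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 for identical partitions (up to label
#'   permutation), about 0 for independent ones.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) stop("cannot compute ARI of empty labelings")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

# A list-column element is "missing" when NULL or a single NA; an observed
# empty set is character(0). The distinction matters for discharge records.
is_missing_set <- function(x) {
  is.null(x) || (length(x) == 1 && is.na(x))
}

# Non-empty observed set?
has_terms <- function(x) {
  !is_missing_set(x) && length(x) > 0
}

# Coerce a list-column element to a clean character set (deduplicated,
# empties removed); missing stays NULL.
as_term_set <- function(x) {
  if (is_missing_set(x)) return(NULL)
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

stop_psn <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "psnstrat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
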