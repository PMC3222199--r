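#' Weighted monotone (isotonic) regression
#'
#' Least-squares fit of a set of category targets under a nondecreasing
#' constraint, weighted by category frequencies, via the pool-adjacent-
#' violators algorithm. This is the transform that quantifies ordinal
#' variables inside the optimal-scaling PCA: it is the closest set of values
#' to the unconstrained category targets that preserves the declared category
#' order. Ties between adjacent violating blocks are pooled to their weighted
#' mean.
#'
#' @param targets Numeric vector of category targets, in category order.
#' @param weights Positive weights (category frequencies); defaults to 1.
#' @return Numeric vector of fitted values, nondecreasing, minimizing
#'   `sum(weights * (fit - targets)^2)` over all nondecreasing vectors.
#' @examples
#' monotone_regression(c(3, 1, 2))            # 2 2 2
#' monotone_regression(c(2, 0), c(2, 1))      # 4/3 4/3
#' @export
monotone_regression <- function(targets, weights = NULL) {
  n <- length(targets)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) rlang::abort("targets and weights differ in length")
  if (!all(is.finite(targets))) rlang::abort("targets must be finite")
  if (!all(is.finite(weights)) || any(weights <= 0)) {
    rlang::abort("weights must be positive and finite")
  }
  if (n == 0) return(numeric())
  # block-merging stack: val/w/len describe pooled level sets
  val <- numeric(n); w <- numeric(n); len <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- targets[i]; w[top] <- weights[i]; len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      tw <- w[top - 1L] + w[top]
      val[top - 1L] <- (val[top - 1L] * w[top - 1L] + val[top] * w[top]) / tw
      w[top - 1L] <- tw
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = len[seq_len(top)])
}
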