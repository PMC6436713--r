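#' @keywords internal
"_PACKAGE"

# Smallest probability admitted before taking logs; avoids -Inf from
# underflow in extreme tails while leaving exact zeros impossible.
.PROB_FLOOR <- 1e-300

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer mixing keeping results below 2^31 so they remain
#' valid R integers.
#' @param seed master integer seed
#' @param index non-negative stream index
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + 12345 * (index + 1)) %% 2147483647L)
}

#' Draw one categorical outcome per row of a probability matrix
#' @param prob n x K matrix of row-stochastic probabilities
#' @return integer vector in 1..K
#' @keywords internal
sample_categorical <- function(prob) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- stats::runif(nrow(prob))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

#' Sum a per-row quantity into groups 1..n_groups
#' @keywords internal
group_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  if (length(x) == 0L) return(out)
  s <- rowsum(x, group, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
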