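#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat for one parameter from two or more chains of
#' equal length: with within-chain variance `W`, between-chain variance `B`
#' (of the chain means, times chain length), the pooled variance estimate is
#' `(n-1)/n * W + B/n` and R-hat is the square root of its ratio to `W`.
#'
#' @param draws a list of numeric vectors (one per chain, equal lengths) or
#'   a matrix with one column per chain.
#' @return The potential scale reduction factor. If all draws are identical
#'   across all chains (zero within-chain variance), 1.0 is returned by
#'   convention.
#' @examples
#' set.seed(1)
#' gelman_rubin(list(rnorm(1000), rnorm(1000)))
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  m <- length(draws)
  if (m < 2L) stop("at least 2 chains are required")
  n <- unique(lengths(draws))
  if (length(n) != 1L) stop("chains must have equal lengths")
  if (n < 2L) stop("chains must have length >= 2")
  means <- vapply(draws, mean, 0)
  vars <- vapply(draws, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Equal-tail credible interval from posterior draws
#'
#' Empirical central interval: the `(1-level)/2` and `1-(1-level)/2`
#' percentiles of the draws under the linear-interpolation (type 7)
#' quantile rule.
#'
#' @param draws numeric vector of posterior draws (at least 2).
#' @param level interval probability (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' equal_tail_interval(1:1000) # c(25.975, 975.025)
#' @export
equal_tail_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop("need at least 2 draws")
  stopifnot(level > 0, level < 1)
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}
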