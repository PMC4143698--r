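#' Effective sample size of an MCMC chain
#'
#' Spectral estimate: `n * var(x) / S(0)`, with the spectral density at
#' frequency zero obtained from an AIC-selected autoregressive fit
#' (`stats::ar`). Constant chains (e.g. a clamped variance) return `n`.
#'
#' @param x Numeric chain.
#' @return Effective sample size.
#' @export
ess_spectral <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(as.numeric(n))
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50, n - 1)),
             silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0) return(as.numeric(n))
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, n * v / spec0)
}

#' Monte Carlo standard error of a chain's mean
#' @param x Numeric chain.
#' @return `sd(x) / sqrt(ESS)`.
#' @export
mc_se <- function(x) stats::sd(x) / sqrt(ess_spectral(x))

#' Split-chain rank-normalized R-hat
#'
#' The chain is split in half, values are rank-normalized with the usual
#' (rank - 3/8) / (n + 1/4) normal scores, and the classical potential
#' scale reduction factor is computed on the two half-chains. Values near 1
#' indicate stationarity; > 1.05 is suspect.
#'
#' @param x Numeric chain (even length recommended).
#' @return R-hat; `NA` for constant chains.
#' @export
split_rhat <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  m <- n %/% 2
  z <- stats::qnorm((rank(x[seq_len(2 * m)]) - 3 / 8) / (2 * m + 1 / 4))
  halves <- matrix(z, ncol = 2)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- m * stats::var(means)
  W <- mean(vars)
  sqrt(((m - 1) / m * W + B / m) / W)
}
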