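#' Spectral density of a chain at frequency zero
#'
#' Fits an autoregressive model by Yule-Walker with AIC order selection
#' and evaluates the implied spectral density at frequency zero,
#' `sigma2 / (1 - sum(phi))^2`. This is the long-run variance used to
#' normalize the Heidelberger-Welch statistics and the effective Monte
#' Carlo standard error `sqrt(spectrum0_ar(x) / length(x))`.
#'
#' @param x numeric chain.
#' @return estimated spectral density at zero.
#' @export
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (var(x) == 0) return(0)
  fit <- ar(x, aic = TRUE, order.max = NULL, method = "yule-walker")
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Cramer-von Mises distribution function
#'
#' CDF of the asymptotic null distribution of the Cramer-von Mises
#' statistic, evaluated by the classical Bessel-function series
#' (four terms, accurate to ~1e-5 over the practical range).
#'
#' @param q quantile(s) (> 0).
#' @return `P(W <= q)`.
#' @export
pcramer <- function(q) {
  vapply(q, function(qq) {
    if (!is.finite(qq) || qq <= 0) return(0)
    s <- 0
    for (k in 0:3) {
      z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(qq))
      u <- (4 * k + 1)^2 / (16 * qq)
      if (u < 700) s <- s + z * exp(-u) * besselK(u, 0.25)
    }
    min(max(s, 0), 1)
  }, numeric(1))
}

#' Heidelberger-Welch stationarity and halfwidth diagnostic
#'
#' Stationarity: a Cramer-von Mises test on the Brownian-bridge transform
#' of partial sums, normalized by the spectral density at zero estimated
#' from the second half of the chain. If the full chain fails at level
#' `pvalue`, the first 10% is discarded and the test repeated, up to a
#' maximum discard of 50%. Halfwidth: on the retained portion, the
#' half-width of the 95% interval for the mean
#' (`1.96 * sqrt(spectrum0_ar(x) / n)`) must be at most `eps` times the
#' mean's magnitude.
#'
#' @param x numeric chain of stored (thinned) samples.
#' @param eps relative halfwidth threshold.
#' @param pvalue significance level of the stationarity test.
#' @return list with `stationarity_passed`, `stationarity_pvalue` (at the
#'   retained window), `full_chain_pvalue` (no discard), `start` (first
#'   retained sample), `mean`, `halfwidth`, `halfwidth_passed`.
#' @export
heidel_welch <- function(x, eps = 0.1, pvalue = 0.05) {
  x <- as.numeric(x)
  n0 <- length(x)
  if (n0 < 100) stop("chain too short for Heidelberger-Welch diagnostics")
  if (var(x) == 0) {
    ## degenerate chain: trivially stationary, zero halfwidth
    return(list(stationarity_passed = TRUE, stationarity_pvalue = 1,
                full_chain_pvalue = 1, start = 1L, mean = mean(x),
                halfwidth = 0, halfwidth_passed = TRUE))
  }
  S0 <- spectrum0_ar(x[(n0 %/% 2):n0])
  ## candidate start points: discard 0%, 10%, ..., 50% of the chain
  starts <- unique(floor(seq(1, n0 / 2 + 1, length.out = 6)))
  passed <- FALSE
  pval <- NA_real_
  full_p <- NA_real_
  kept <- x
  start <- starts[1]
  for (s in starts) {
    y <- x[s:n0]
    n <- length(y)
    Bt <- cumsum(y) - mean(y) * seq_len(n)
    I <- sum(Bt^2 / (n * S0)) / n
    p <- 1 - pcramer(I)
    if (s == starts[1]) full_p <- p
    if (p > pvalue) {
      passed <- TRUE
      pval <- p
      kept <- y
      start <- s
      break
    }
    pval <- p
    start <- s
    kept <- y
  }
  mn <- mean(kept)
  hw <- 1.96 * sqrt(spectrum0_ar(kept) / length(kept))
  list(stationarity_passed = passed, stationarity_pvalue = pval,
       full_chain_pvalue = full_p, start = as.integer(start), mean = mn,
       halfwidth = hw, halfwidth_passed = is.finite(hw) &&
         (hw == 0 || abs(hw / mn) <= eps))
}

#' Convergence diagnostics for a posterior chain
#'
#' For every scalar parameter of the chain (trait means and unique
#' component-matrix elements): lag-1 autocorrelation of the thinned chain,
#' the Heidelberger-Welch stationarity test, and the halfwidth test.
#'
#' @param chain a `posterior_chain` with at least 100 stored samples.
#' @param eps,pvalue see [heidel_welch()].
#' @return data frame with one row per parameter and a `passed` flag
#'   (stationarity and halfwidth both passed).
#' @export
convergence_diagnostics <- function(chain, eps = 0.1, pvalue = 0.05) {
  X <- as.matrix(chain)
  if (nrow(X) < 100) stop("need >= 100 stored samples for diagnostics")
  out <- lapply(colnames(X), function(nm) {
    x <- X[, nm]
    ac1 <- if (var(x) == 0) 0 else cor(x[-1], x[-length(x)])
    hw <- heidel_welch(x, eps, pvalue)
    data.frame(parameter = nm, lag1_autocorr = ac1,
               stationarity_passed = hw$stationarity_passed,
               stationarity_pvalue = hw$stationarity_pvalue,
               start = hw$start, mean = hw$mean, halfwidth = hw$halfwidth,
               halfwidth_passed = hw$halfwidth_passed,
               passed = hw$stationarity_passed && hw$halfwidth_passed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
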