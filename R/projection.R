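#' Single-generation selection response
#'
#' The multivariate breeder's (Lande) equation: the per-generation change
#' in trait means is `delta_z = G %*% beta`, where `G` is the additive
#' genetic (co)variance matrix and `beta` the vector of selection
#' gradients. With selection acting only on one trait (e.g. mortality
#' under ambient conditions, `beta = c(-0.10, 0)`), the other component of
#' `delta_z` is the correlated response — here, the "priming" of tolerance
#' to conditions the population has not yet experienced.
#'
#' @param G symmetric positive-semidefinite genetic covariance matrix.
#' @param beta numeric selection-gradient vector, same dimension as `G`.
#' @return numeric vector `delta_z` (named after `G`'s columns if any).
#' @examples
#' G <- matrix(c(2.48e-4, 2.10e-4, 2.10e-4, 7.23e-4), 2, 2)
#' selection_response(G, c(-0.10, 0))  # -2.48e-5 (direct), -2.10e-5 (correlated)
#' @export
selection_response <- function(G, beta) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) stop("G must be a square matrix")
  if (length(beta) != nrow(G)) {
    stop("beta length must match the dimension of G")
  }
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
    stop("G must be symmetric")
  }
  drop(G %*% beta)
}

#' Posterior distribution of selection responses
#'
#' Propagates posterior uncertainty in G through the selection-response
#' calculation: `G %*% beta` per stored sample, summarized by posterior
#' mean and interval per trait.
#'
#' @param chain a `posterior_chain`.
#' @param beta selection-gradient vector (length 4, trait order as in the
#'   chain).
#' @param prob interval probability.
#' @param interval `"hpd"` or `"quantile"`.
#' @return data frame with one row per trait: `mean`, `lower`, `upper`;
#'   the per-sample response matrix is attached as attribute `"samples"`.
#' @export
posterior_response <- function(chain, beta, prob = 0.95, interval = "hpd") {
  tn <- chain$trait_names
  stopifnot(length(beta) == length(tn))
  ns <- chain$n_samples
  resp <- t(vapply(seq_len(ns),
                   function(s) drop(chain$G[, , s] %*% beta),
                   numeric(length(tn))))
  out <- do.call(rbind, lapply(seq_along(tn), function(t) {
    s <- posterior_summary(resp[, t], prob, interval)
    data.frame(trait = tn[t], mean = s$mean, lower = s$lower,
               upper = s$upper, stringsAsFactors = FALSE)
  }))
  attr(out, "samples") <- resp
  out
}
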