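resolve_trait <- function(chain, trait) {
  if (is.character(trait)) {
    i <- match(trait, chain$trait_names)
    if (is.na(i)) stop("unknown trait: ", trait)
    i
  } else {
    as.integer(trait)
  }
}

posterior_summary <- function(samples, prob = 0.95,
                              interval = c("hpd", "quantile")) {
  interval <- match.arg(interval)
  ci <- if (interval == "hpd") {
    hpd_interval(samples, prob)
  } else {
    unname(quantile(samples, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  }
  list(mean = mean(samples), lower = ci[1], upper = ci[2],
       prob = prob, interval = interval, samples = samples)
}

#' Posterior heritability of a trait
#'
#' Heritability is the additive genetic proportion of the total modeled
#' phenotypic variance, computed per posterior sample as
#' `h2 = G[t, t] / (G[t, t] + M[t, t] + B[t, t] + R[t, t])` and then
#' summarized (posterior mean and 95% highest-posterior-density interval).
#'
#' @param chain a `posterior_chain`.
#' @param trait trait name or index.
#' @param prob interval probability.
#' @param interval `"hpd"` or `"quantile"`.
#' @return list with `mean`, `lower`, `upper` and the per-sample values.
#' @export
heritability <- function(chain, trait, prob = 0.95, interval = "hpd") {
  t <- resolve_trait(chain, trait)
  h2 <- chain$G[t, t, ] /
    (chain$G[t, t, ] + chain$M[t, t, ] + chain$B[t, t, ] + chain$R[t, t, ])
  posterior_summary(h2, prob, interval)
}

#' Posterior variance proportions of all components
#'
#' Expresses each component's variance as a proportion of the per-sample
#' total (the four proportions of a trait sum to one in every sample) and
#' summarizes each.
#'
#' @inheritParams heritability
#' @return data frame with one row per trait x component: posterior `mean`,
#'   `lower`, `upper`.
#' @export
variance_proportions <- function(chain, prob = 0.95, interval = "hpd") {
  tn <- chain$trait_names
  out <- list()
  for (t in seq_along(tn)) {
    tot <- chain$G[t, t, ] + chain$M[t, t, ] + chain$B[t, t, ] +
      chain$R[t, t, ]
    for (comp in c("G", "M", "B", "R")) {
      s <- posterior_summary(chain[[comp]][t, t, ] / tot, prob, interval)
      out[[length(out) + 1L]] <- data.frame(
        trait = tn[t], component = comp, mean = s$mean,
        lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

component_correlation <- function(chain, comp, trait_x, trait_y, prob,
                                  interval) {
  i <- resolve_trait(chain, trait_x)
  j <- resolve_trait(chain, trait_y)
  V <- chain[[comp]]
  r <- V[i, j, ] / sqrt(V[i, i, ] * V[j, j, ])
  posterior_summary(r, prob, interval)
}

#' Posterior genetic correlation between two traits
#'
#' Per sample, `r_G = Cov_A(x, y) / sqrt(V_A(x) * V_A(y))` from the G
#' matrix; always in `[-1, 1]` because every stored G is positive
#' semidefinite. For the same trait expressed in the two environments,
#' `r_G < 1` signals a genotype-by-environment interaction.
#'
#' @inheritParams heritability
#' @param trait_x,trait_y trait names or indices.
#' @export
genetic_correlation <- function(chain, trait_x, trait_y, prob = 0.95,
                                interval = "hpd") {
  component_correlation(chain, "G", trait_x, trait_y, prob, interval)
}

#' Posterior maternal-effect correlation between two traits
#'
#' As [genetic_correlation()] but on the maternal component M.
#'
#' @inheritParams genetic_correlation
#' @export
maternal_correlation <- function(chain, trait_x, trait_y, prob = 0.95,
                                 interval = "hpd") {
  component_correlation(chain, "M", trait_x, trait_y, prob, interval)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `prob` of the samples:
#' among all windows of `ceiling(prob * n)` order statistics, the one with
#' the smallest width (leftmost on ties).
#'
#' @param samples numeric vector (>= 20 values recommended).
#' @param prob interval probability.
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  stopifnot(length(samples) >= 2, prob > 0, prob <= 1)
  x <- sort(samples)
  n <- length(x)
  m <- min(n, max(2L, ceiling(prob * n)))
  i <- seq_len(n - m + 1L)
  w <- x[i + m - 1L] - x[i]
  k <- which.min(w)  # leftmost minimal window
  c(x[k], x[k + m - 1L])
}

#' Flatten a posterior chain to a sample-by-parameter matrix
#'
#' One row per stored sample; columns are the trait means and the unique
#' (lower-triangle) elements of each component matrix, named e.g.
#' `G.mortality_ambient.mortality_acidified`.
#'
#' @param x a `posterior_chain`.
#' @param ... unused.
#' @return numeric matrix.
#' @export
as.matrix.posterior_chain <- function(x, ...) {
  tn <- x$trait_names
  p <- length(tn)
  cols <- list()
  for (t in seq_len(p)) cols[[paste0("mu.", tn[t])]] <- x$mu[, t]
  for (comp in c("G", "M", "B", "R")) {
    for (i in seq_len(p)) for (j in seq_len(i)) {
      cols[[paste(comp, tn[i], tn[j], sep = ".")]] <- x[[comp]][i, j, ]
    }
  }
  do.call(cbind, cols)
}

#' Write a posterior chain as CSV
#'
#' Columnar layout: one row per stored sample, one column per scalar
#' parameter (see [as.matrix.posterior_chain()] for the column order).
#'
#' @param chain a `posterior_chain`.
#' @param path output file.
#' @export
write_chain <- function(chain, path) {
  write.csv(as.data.frame(as.matrix(chain)), path, row.names = FALSE)
  invisible(path)
}
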