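#' Model specification for the multivariate animal model
#'
#' Assembles the data structures the Gibbs sampler needs: the trait
#' response matrix with its observed mask, the record-to-pseudo-individual,
#' record-to-dam and record-to-block index maps, and the pedigree
#' relationship matrix inverse.
#'
#' @param trait_table a `trait_table` (from [build_trait_table()] or
#'   [simulate_trait_values()]).
#' @param ped a [pedigree] containing every `individual` in the table.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(trait_table, ped) {
  stopifnot(inherits(ped, "pedigree"))
  tn <- oaq_trait_names()
  stopifnot(all(tn %in% names(trait_table)))
  Y <- as.matrix(trait_table[tn])
  obs <- as.matrix(trait_table[paste0("obs_", tn)])
  storage.mode(obs) <- "logical"
  obs <- obs & !is.na(Y)
  if (any(rowSums(obs) == 0)) stop("every record must observe >= 1 trait")
  ind <- match(trait_table$individual, ped$id)
  if (anyNA(ind)) stop("records reference individuals missing from the pedigree")
  dams <- sort(unique(trait_table$dam))
  blocks <- sort(unique(trait_table$block))
  ## pedigree index of each dam level (0 -> unknown); only usable for the
  ## sampler's recentering moves when the record's dam matches the
  ## pedigree dam of its pseudo-individual
  dam_ped <- match(dams, ped$id)
  ped_dam_of_rec <- ped$id[ped$dam[ind]]
  consistent <- !anyNA(ped_dam_of_rec) &&
    all(ped_dam_of_rec == trait_table$dam)
  if (!consistent) dam_ped[] <- NA
  dam_ped[is.na(dam_ped)] <- 0L
  A <- additive_relationship_matrix(ped)
  noninbred <- all(abs(diag(A) - 1) < 1e-12)
  A_inv <- if (noninbred) henderson_a_inverse(ped) else {
    warning("inbred pedigree detected; using dense inversion of A")
    solve(A)
  }
  structure(list(
    trait_names = tn,
    Y = Y, obs = obs,
    ind = ind,
    dam = match(trait_table$dam, dams),
    blk = match(trait_table$block, blocks),
    dam_levels = dams, block_levels = blocks,
    dam_ped = dam_ped,
    ped = ped,
    noninbred = noninbred,
    A_inv = A_inv
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("animal-model spec:", nrow(x$Y), "records,",
      length(x$ped$id), "pedigree members,",
      length(x$dam_levels), "dams,", length(x$block_levels), "blocks\n")
  invisible(x)
}

#' Weakly informative inverse-Wishart priors from observed variances
#'
#' For each of the four components (G, M, B, R) the prior is
#' inverse-Wishart with scale `nu * V0` and degree of belief `nu`, where
#' `V0` is diagonal with entries one quarter of the observed per-trait
#' phenotypic variance (prior modal covariances zero). With the default
#' `nu = 0.001` the priors are very wide and flat: the prior mode
#' `nu * V0 / (nu + p + 1)` is vanishingly small and the data dominate.
#'
#' @param trait_table a trait table; variances are computed from observed
#'   cells only.
#' @param nu degree-of-belief parameter (> 0).
#' @return an object of class `"prior_spec"`: per component, `V` (4 x 4),
#'   `nu`, and the sampler scale `S = nu * V`.
#' @export
prior_from_data <- function(trait_table, nu = 0.001) {
  stopifnot(nu > 0)
  tn <- oaq_trait_names()
  v <- vapply(tn, function(t) {
    x <- trait_table[[t]][trait_table[[paste0("obs_", t)]]]
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("need >= 2 observed values for trait ", t)
    var(x)
  }, numeric(1))
  if (any(v <= 0)) stop("zero observed variance in trait(s): ",
                        paste(tn[v <= 0], collapse = ", "))
  V0 <- diag(v / 4, 4)
  dimnames(V0) <- list(tn, tn)
  comp <- list(V = V0, nu = nu, S = nu * V0)
  structure(list(G = comp, M = comp, B = comp, R = comp, trait_names = tn),
            class = "prior_spec")
}

#' Number of stored MCMC samples
#'
#' @param n_iter total iterations.
#' @param burn_in burn-in interval.
#' @param thin thinning period.
#' @return `floor((n_iter - burn_in) / thin)`.
#' @examples
#' chain_length(150000, 1000, 80)  # 1862
#' @export
chain_length <- function(n_iter, burn_in, thin) {
  stopifnot(n_iter > burn_in, thin >= 1)
  floor((n_iter - burn_in) / thin)
}

#' Inverse-Wishart sample
#'
#' Draws from the inverse-Wishart distribution with density proportional
#' to `|S|^{-(df + p + 1)/2} exp(-tr(Scale S^{-1}) / 2)`; the mean is
#' `Scale / (df - p - 1)` for `df > p + 1`.
#'
#' @param df degrees of freedom (> p - 1).
#' @param Scale symmetric positive-definite scale matrix.
#' @return one sampled covariance matrix.
#' @export
riwishart <- function(df, Scale) {
  riwish_core(df, Scale)
}

#' Fit the multivariate animal model by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler for the four-trait animal model
#' `y = mu + a + m + b + e` partitioning phenotypic (co)variance into
#' additive genetic (`G`), maternal (`M`), block (`B`) and residual (`R`)
#' 4 x 4 components. Each sweep (i) imputes the structurally unobserved
#' traits of every record from their conditional normal, (ii) samples the
#' trait means, (iii) samples additive, maternal and block effect vectors
#' from their normal full conditionals (additive effects use the sparse
#' relationship-matrix inverse), and (iv) samples each component from its
#' inverse-Wishart full conditional. Every `thin`-th post-burn-in state is
#' stored.
#'
#' @param model a [model_spec].
#' @param prior a [prior_spec].
#' @param n_iter,burn_in,thin chain settings (`n_iter > burn_in`).
#' @param seed integer seed; chains are bit-for-bit reproducible.
#' @param fixed optional named list pinning parts of the model, e.g.
#'   `list(G = matrix0, mu = c(...))`: a fixed component is not updated
#'   and, if it is the zero matrix, its effects are dropped. Used for
#'   degenerate single-component models and conjugacy checks.
#' @param impute logical; impute unobserved traits (data augmentation).
#'   Automatically disabled when all traits are observed.
#' @return an object of class `"posterior_chain"`: arrays `G`, `M`, `B`,
#'   `R` (`4 x 4 x n_samples`), matrix `mu` (`n_samples x 4`), and chain
#'   metadata.
#' @export
run_gibbs <- function(model, prior, n_iter = 150000, burn_in = 1000,
                      thin = 80, seed = 1, fixed = list(), impute = TRUE,
                      collapsed_G = TRUE) {
  stopifnot(inherits(model, "model_spec"), inherits(prior, "prior_spec"),
            n_iter > burn_in, thin >= 1)
  tn <- model$trait_names
  p <- length(tn)
  Y <- model$Y
  obs <- model$obs
  impute <- impute && any(!obs)

  ## initial values: observed column means fill unobserved cells
  colmu <- vapply(seq_len(p), function(t) mean(Y[obs[, t], t]), numeric(1))
  for (t in seq_len(p)) Y[!obs[, t], t] <- colmu[t]
  colv <- vapply(seq_len(p), function(t) var(Y[obs[, t], t]), numeric(1))
  colv[!is.finite(colv) | colv <= 0] <- 1

  init <- function(name, default) {
    if (!is.null(fixed[[name]])) fixed[[name]] else default
  }
  start <- diag(colv / 4, p)
  G0 <- init("G", start)
  M0 <- init("M", start)
  B0 <- init("B", start)
  R0 <- init("R", diag(colv / 4, p))
  mu0 <- init("mu", colmu)
  is_zero <- function(V) all(abs(V) < .Machine$double.eps)

  ## a sampled component's inverse-Wishart full conditional is proper only
  ## when prior nu + number of effect levels exceeds p - 1
  lv <- c(G = length(model$ped$id), M = length(model$dam_levels),
          B = length(model$block_levels), R = nrow(Y))
  for (nm in names(lv)) {
    if (is.null(fixed[[nm]]) && prior[[nm]]$nu + lv[[nm]] <= p - 1) {
      stop("component ", nm, " has too few levels (", lv[[nm]],
           ") for a proper full conditional with nu = ", prior[[nm]]$nu)
    }
  }

  set.seed(seed)
  res <- gibbs_core(
    Y, obs * 1L, model$ind - 1L, model$dam - 1L, model$blk - 1L,
    model$A_inv,
    length(model$dam_levels), length(model$block_levels),
    prior$G$S, prior$M$S, prior$B$S, prior$R$S,
    prior$G$nu, prior$M$nu, prior$B$nu, prior$R$nu,
    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
    is.null(fixed$G), is.null(fixed$M), is.null(fixed$B), is.null(fixed$R),
    is.null(fixed$mu),
    !is_zero(G0), !is_zero(M0), !is_zero(B0),
    impute,
    G0, M0, B0, R0, mu0,
    ifelse(is.na(model$ped$sire), -1L, model$ped$sire - 1L),
    ifelse(is.na(model$ped$dam), -1L, model$ped$dam - 1L),
    model$dam_ped - 1L,
    isTRUE(model$noninbred) && isTRUE(collapsed_G))

  dn <- list(tn, tn, NULL)
  for (nm in c("G", "M", "B", "R")) dimnames(res[[nm]]) <- dn
  colnames(res$mu) <- tn
  structure(list(G = res$G, M = res$M, B = res$B, R = res$R, mu = res$mu,
                 n_samples = res$n_stored, n_iter = n_iter,
                 burn_in = burn_in, thin = thin, seed = seed,
                 trait_names = tn),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior chain:", x$n_samples, "stored samples",
      sprintf("(%d iterations, burn-in %d, thin %d, seed %d)\n",
              x$n_iter, x$burn_in, x$thin, x$seed))
  invisible(x)
}
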