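test_that("chain bookkeeping follows floor((n_iter - burn_in) / thin)", {
  expect_equal(chain_length(150000, 1000, 80), 1862)
  expect_equal(chain_length(2000, 200, 5), 360)
  expect_error(chain_length(100, 200, 5), "n_iter > burn_in")
  ## an actual run stores exactly that many samples
  prob <- small_fitted_problem(n_blocks = 6)
  ch <- run_gibbs(prob$model, prob$prior, n_iter = 500, burn_in = 100,
                  thin = 7, seed = 2)
  expect_equal(ch$n_samples, chain_length(500, 100, 7))
  expect_equal(dim(ch$G), c(4, 4, ch$n_samples))
})

test_that("priors put quarter-variance modes with the stated belief", {
  prob <- small_fitted_problem()
  pr <- prior_from_data(prob$traits)
  v <- vapply(oaquant:::oaq_trait_names(), function(t) {
    x <- prob$traits[[t]][prob$traits[[paste0("obs_", t)]]]
    var(x)
  }, numeric(1))
  expect_equal(unname(diag(pr$G$V)), unname(v) / 4)
  expect_true(all(pr$G$V[upper.tri(pr$G$V)] == 0))
  expect_equal(pr$G$nu, 0.001)
  expect_equal(pr$R$S, 0.001 * pr$R$V)
  ## doubling the data quadruples the prior variances
  tt2 <- prob$traits
  for (t in oaquant:::oaq_trait_names()) tt2[[t]] <- 2 * tt2[[t]]
  pr2 <- prior_from_data(tt2)
  expect_equal(diag(pr2$G$V), 4 * diag(pr$G$V))
  ## constant trait errors
  tt3 <- prob$traits
  tt3$mortality_ambient[] <- 0.05
  expect_error(prior_from_data(tt3), "zero observed variance")
})

test_that("inverse-Wishart sampler has the analytic mean", {
  set.seed(1)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  df <- 20
  draws <- replicate(3000, riwishart(df, S))
  anal <- S / (df - 4 - 1)
  err <- apply(draws, 1:2, mean) - anal
  mcse <- apply(draws, 1:2, sd) / sqrt(3000)
  expect_true(all(abs(err) < 4 * mcse + 1e-12))
  ## every draw symmetric positive definite
  expect_true(all(apply(draws, 3, function(X) {
    isSymmetric(X, tol = 1e-10) &&
      min(eigen(X, only.values = TRUE)$values) > 0
  })))
})

test_that("degenerate residual-only model matches the conjugate posterior", {
  ## with G = M = B = 0 fixed and a known mean, the residual component's
  ## full conditional is sampled fresh each sweep: draws are iid from
  ## IW(nu + n, S + crossprod(Y - mu))
  set.seed(42)
  n <- 200
  Rtrue <- matrix(0.5, 4, 4) + diag(0.5, 4)
  Y <- matrix(rnorm(n * 4), n, 4) %*% chol(Rtrue)
  tn <- oaquant:::oaq_trait_names()
  tt <- data.frame(tank_id = sprintf("t%d", 1:n), individual = "f1",
                   dam = "d1", block = "b1", treatment = "ambient",
                   stringsAsFactors = FALSE)
  tt <- cbind(tt, stats::setNames(as.data.frame(Y), tn),
              stats::setNames(as.data.frame(matrix(TRUE, n, 4)),
                              paste0("obs_", tn)))
  class(tt) <- c("trait_table", "data.frame")
  ms <- model_spec(tt, pedigree("f1"))
  pr <- prior_from_data(tt)
  z4 <- matrix(0, 4, 4)
  ch <- run_gibbs(ms, pr, n_iter = 3000, burn_in = 0, thin = 1, seed = 9,
                  fixed = list(G = z4, M = z4, B = z4, mu = rep(0, 4)))
  Spost <- pr$R$S + crossprod(Y)
  anal <- Spost / (pr$R$nu + n - 4 - 1)
  emp <- apply(ch$R, 1:2, mean)
  mcse <- apply(ch$R, 1:2, sd) / sqrt(ch$n_samples)
  expect_true(all(abs(emp - anal) < 4 * mcse))
  ## iid draws: negligible autocorrelation
  x <- ch$R[1, 1, ]
  expect_lt(abs(cor(x[-1], x[-length(x)])), 0.1)
})

test_that("chains are bit-for-bit reproducible under a fixed seed", {
  prob <- small_fitted_problem(n_blocks = 6)
  ch1 <- run_gibbs(prob$model, prob$prior, n_iter = 400, burn_in = 50,
                   thin = 5, seed = 77)
  ch2 <- run_gibbs(prob$model, prob$prior, n_iter = 400, burn_in = 50,
                   thin = 5, seed = 77)
  expect_identical(as.matrix(ch1), as.matrix(ch2))
  ch3 <- run_gibbs(prob$model, prob$prior, n_iter = 400, burn_in = 50,
                   thin = 5, seed = 78)
  expect_false(identical(as.matrix(ch1), as.matrix(ch3)))
})

test_that("stored components are symmetric PSD and summaries behave", {
  prob <- small_fitted_problem(n_blocks = 6)
  ch <- run_gibbs(prob$model, prob$prior, n_iter = 600, burn_in = 100,
                  thin = 5, seed = 3)
  for (comp in c("G", "M", "B", "R")) {
    ok <- apply(ch[[comp]], 3, function(X) {
      isSymmetric(X, tol = 1e-8) &&
        min(eigen(X, only.values = TRUE)$values) > -1e-10
    })
    expect_true(all(ok))
  }
  ## proportions sum to one per sample; correlations bounded
  tot <- ch$G[1, 1, ] + ch$M[1, 1, ] + ch$B[1, 1, ] + ch$R[1, 1, ]
  props <- cbind(ch$G[1, 1, ], ch$M[1, 1, ], ch$B[1, 1, ], ch$R[1, 1, ]) / tot
  expect_equal(rowSums(props), rep(1, nrow(props)), tolerance = 1e-12)
  rg <- genetic_correlation(ch, 1, 2)$samples
  expect_true(all(rg >= -1 & rg <= 1))
  rm <- maternal_correlation(ch, 1, 2)$samples
  expect_true(all(rm >= -1 & rm <= 1))
})

test_that("derived summaries reduce correctly on point chains", {
  ## hand-built single-sample chain from a fixed G matrix
  G <- matrix(c(2.48e-4, 2.10e-4, 0, 0,
                2.10e-4, 7.23e-4, 0, 0,
                0, 0, 1e-4, 0,
                0, 0, 0, 1e-4), 4, 4)
  eq <- diag(c(1, 1, 1, 1)) * 1e-4
  ch <- structure(list(
    G = array(G, c(4, 4, 2)), M = array(eq, c(4, 4, 2)),
    B = array(eq, c(4, 4, 2)), R = array(eq, c(4, 4, 2)),
    mu = matrix(0, 2, 4), n_samples = 2,
    trait_names = oaquant:::oaq_trait_names()), class = "posterior_chain")
  ## r_G from the estimated mortality G matrix: 2.10 / sqrt(2.48 * 7.23)
  expect_equal(genetic_correlation(ch, 1, 2)$mean, 0.496, tolerance = 5e-4)
  expect_equal(genetic_correlation(ch, 3, 4)$mean, 0)  # diagonal block
  expect_equal(genetic_correlation(ch, 1, 1)$mean, 1)  # self-correlation
  expect_equal(maternal_correlation(ch, 1, 2)$mean, 0)
  expect_equal(maternal_correlation(ch, 2, 2)$mean, 1)
  ## equal components: each proportion 1/4; h2 = 1/4 where G matches
  vp <- variance_proportions(ch)
  g3 <- vp[vp$trait == "growth_ambient", ]
  expect_equal(g3$mean, rep(0.25, 4))
  expect_equal(heritability(ch, 3)$mean, 0.25)
})

test_that("proportions and correlations are invariant to trait rescaling", {
  ## the model and prior construction are equivariant under per-trait
  ## rescaling, so scale-free summaries must agree up to Monte-Carlo error
  ## (chains are not bit-identical: slice moves consume data-dependent
  ## amounts of randomness)
  prob <- small_fitted_problem(n_blocks = 12)
  tt2 <- prob$traits
  sc <- c(10, 0.5, 2, 100)
  tn <- oaquant:::oaq_trait_names()
  for (t in seq_len(4)) tt2[[tn[t]]] <- tt2[[tn[t]]] * sc[t]
  ms2 <- model_spec(tt2, prob$design$pedigree)
  pr1 <- prior_from_data(prob$traits, nu = 5)
  pr2 <- prior_from_data(tt2, nu = 5)
  expect_equal(diag(pr2$G$V), diag(pr1$G$V) * sc^2)  # prior equivariance
  ch1 <- run_gibbs(prob$model, pr1, n_iter = 4000, burn_in = 1000,
                   thin = 3, seed = 21)
  ch2 <- run_gibbs(ms2, pr2, n_iter = 4000, burn_in = 1000,
                   thin = 3, seed = 22)
  h1 <- heritability(ch1, 1)
  h2 <- heritability(ch2, 1)
  expect_lt(abs(h1$mean - h2$mean), 0.06)
  ## HPD intervals overlap substantially
  expect_lt(max(h1$lower, h2$lower), min(h1$upper, h2$upper))
  r1 <- genetic_correlation(ch1, 1, 2)
  r2 <- genetic_correlation(ch2, 1, 2)
  expect_lt(abs(r1$mean - r2$mean), 0.25)
})

test_that("parameter recovery works on a truth-parameterized dataset", {
  ## one moderate dataset; the replicated version runs in the acceptance
  ## suite. Uses the weakest proper prior (nu = p + 1).
  spec <- design_spec(n_blocks = 24, sets_per_block = 2, seed = 31)
  d <- generate_breeding_design(spec)
  truth <- default_truth()
  tt <- simulate_trait_values(d$pedigree, d$tanks, truth, seed = 32)
  ms <- model_spec(tt, d$pedigree)
  pr <- prior_from_data(tt, nu = 5)
  ch <- run_gibbs(ms, pr, n_iter = 6000, burn_in = 1000, thin = 5, seed = 33)
  h <- heritability(ch, "mortality_acidified")
  expect_gt(h$upper, 0.06)   # finds appreciable genetic variance
  expect_lt(h$lower, 0.45)
  rm <- maternal_correlation(ch, 1, 2)
  expect_gt(rm$mean, 0.3)    # strong shared maternal effect recovered
})
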