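test_that("factorial sets produce the expected family counts", {
  d1 <- generate_breeding_design(design_spec(n_blocks = 1, sets_per_block = 1,
                                             seed = 2))
  expect_equal(nrow(d1$families), 9)   # single 3 x 3 set
  d2 <- two_set_design(seed = 2)
  expect_equal(nrow(d2$families), 18)  # two sets in one spawning event
  ## every tank carries family, parents, block, treatment
  expect_true(all(c("tank_id", "family_id", "sire_id", "dam_id", "block",
                    "treatment") %in% names(d2$tanks)))
  expect_true(all(d2$tanks$treatment %in% c("ambient", "acidified")))
})

test_that("capacity and duplication rules shape the tank layout", {
  ## no duplicates and ample capacity: exactly one tank per treatment per family
  d <- generate_breeding_design(design_spec(
    n_blocks = 2, sets_per_block = 1, duplicate_family_fraction = 0,
    max_tanks_per_treatment_per_block = 20, seed = 4))
  tab <- table(d$tanks$family_id, d$tanks$treatment)
  expect_true(all(tab == 1))
  expect_equal(nrow(d$tanks), 2 * 9 * 2)
  ## capacity caps the number of reared families
  d2 <- generate_breeding_design(design_spec(
    n_blocks = 1, sets_per_block = 2, duplicate_family_fraction = 0,
    max_tanks_per_treatment_per_block = 12, seed = 4))
  expect_lte(sum(d2$tanks$treatment == "ambient"), 12)
  ## duplicated families get a second tank in each treatment
  d3 <- generate_breeding_design(design_spec(
    n_blocks = 1, sets_per_block = 1, duplicate_family_fraction = 1,
    max_tanks_per_treatment_per_block = 12, seed = 4))
  tab3 <- table(d3$tanks$family_id, d3$tanks$treatment)
  expect_true(any(tab3 == 2))
  expect_error(design_spec(max_tanks_per_treatment_per_block = 0),
               "positive")
  expect_error(design_spec(duplicate_family_fraction = 1.5), "\\[0, 1\\]")
})

test_that("zero covariance components give exactly the trait means", {
  d <- two_set_design()
  z <- matrix(0, 4, 4)
  truth <- truth_params(mu = c(0.05, 0.06, 1.5, 1.4),
                        G = z, M = z, B = z, R = z)
  tt <- simulate_trait_values(d$pedigree, d$tanks, truth, seed = 1)
  for (t in seq_along(truth$trait_names)) {
    expect_equal(unique(tt[[truth$trait_names[t]]]), truth$mu[t])
  }
  bad <- truth_params(mu = rep(0, 4), G = diag(4), M = z, B = z, R = z)
  bad$G[1, 2] <- bad$G[2, 1] <- 2  # not PSD
  expect_error(simulate_trait_values(d$pedigree, d$tanks, bad, seed = 1),
               "semidefinite")
})

test_that("sib covariances follow the additive expectations", {
  ## G only, diagonal: full-sib tank pairs covary by G/2 and paternal
  ## half-sib pairs by G/4 (brute-force over many independent families)
  z <- matrix(0, 4, 4)
  truth <- truth_params(mu = rep(0, 4), G = diag(4), M = z, B = z, R = z)
  spec <- design_spec(n_blocks = 250, sets_per_block = 1,
                      duplicate_family_fraction = 1,
                      max_tanks_per_treatment_per_block = 18, seed = 9)
  d <- generate_breeding_design(spec)
  tt <- simulate_trait_values(d$pedigree, d$tanks, truth, seed = 10)
  y <- tt$mortality_ambient

  ## full-sib pairs: two tanks of the same family
  fs <- do.call(rbind, lapply(split(seq_len(nrow(tt)), tt[["block"]]),
    function(ix) {
      fam <- split(ix, d$tanks$family_id[ix])
      do.call(rbind, lapply(fam, function(f) {
        if (length(f) >= 2) t(combn(f, 2)) else NULL
      }))
    }))
  expect_gt(nrow(fs), 2000)
  cov_fs <- cov(y[fs[, 1]], y[fs[, 2]])
  se <- sqrt((1 + 0.25) / nrow(fs))  # var ~ (V1 V2 + c^2)/n with V = 1
  expect_lt(abs(cov_fs - 0.5), 3 * se)

  ## paternal half-sib pairs: same sire, different dam, one per family pair
  phs <- do.call(rbind, lapply(split(seq_len(nrow(tt)), tt[["block"]]),
    function(ix) {
      bysire <- split(ix, d$tanks$sire_id[ix])
      do.call(rbind, lapply(bysire, function(s) {
        fams <- split(s, d$tanks$dam_id[s])
        if (length(fams) < 2) return(NULL)
        t(combn(vapply(fams, `[`, integer(1), 1), 2))
      }))
    }))
  expect_gt(nrow(phs), 500)
  cov_phs <- cov(y[phs[, 1]], y[phs[, 2]])
  se2 <- sqrt((1 + 0.0625) / nrow(phs))
  expect_lt(abs(cov_phs - 0.25), 3 * se2)
})

test_that("daily survivor counts follow binomial exponential thinning", {
  expect_identical(simulate_daily_counts(0, 50, 14, seed = 1), rep(50L, 15))
  expect_error(simulate_daily_counts(-0.1, 50, 14), ">= 0")
  ## huge mortality wipes the tank out on day one
  expect_equal(simulate_daily_counts(10, 50, 3, seed = 2)[2], 0)
  ## series are non-increasing integers
  x <- simulate_daily_counts(0.15, 50, 14, seed = 3)
  expect_true(all(diff(x) <= 0), all(x >= 0), is.integer(x))
  ## E[N_14] = 50 exp(-0.7); mean over replicates within 3 SE
  set.seed(4)
  n14 <- replicate(10000, simulate_daily_counts(0.05, 50, 14)[15])
  mu <- 50 * exp(-0.7)
  expect_lt(abs(mean(n14) - mu), 3 * sd(n14) / sqrt(length(n14)))
  ## identical seeds reproduce identical series
  expect_identical(simulate_daily_counts(0.1, 50, 14, seed = 7),
                   simulate_daily_counts(0.1, 50, 14, seed = 7))
})

test_that("length samples have the stated mean difference", {
  l0 <- simulate_lengths(1.5, base_len = 6, n = 10, noise_sd = 0, seed = 1)
  expect_equal(mean(l0$day14) - mean(l0$day0), 1.5)
  ## unbiased growth estimator over replicates
  set.seed(2)
  est <- replicate(10000, {
    l <- simulate_lengths(1.5, 6, 10, 0.2)
    mean(l$day14) - mean(l$day0)
  })
  expect_lt(abs(mean(est) - 1.5), 3 * sd(est) / sqrt(length(est)))
  ## zero growth: difference near zero
  l2 <- simulate_lengths(0, 6, 10, 0.2, seed = 3)
  expect_lt(abs(mean(l2$day14) - mean(l2$day0)), 3 * 0.2 * sqrt(2 / 10))
})

test_that("dataset writer emits the declared CSV files", {
  ds <- simulate_dataset(design_spec(n_blocks = 2, seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  for (f in c("pedigree.csv", "tanks.csv", "counts.csv", "lengths.csv",
              "truth.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  cc <- read.csv(file.path(dir, "counts.csv"))
  expect_true(all(cc$day >= 0))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(unname(unlist(tr$mu)), ds$truth$mu)
})
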