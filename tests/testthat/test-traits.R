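test_that("mortality rate recovers the slope of noiseless exponential decay", {
  for (m in c(0.02, 0.1, 0.2, 0.3)) {
    counts <- round(50 * exp(-m * 0:14))
    expect_lt(abs(mortality_rate(counts) - m), 0.005)
  }
  expect_equal(mortality_rate(rep(50, 15)), 0)
})

test_that("mortality rate truncates at the last positive count", {
  ## zeros from day 5 on: regression must use days 0-4 only
  counts <- c(50, 30, 18, 11, 6, 0, 0, 0)
  expect_equal(mortality_rate(counts),
               mortality_rate(counts[1:5], days = 0:4))
  expect_error(mortality_rate(c(50, 0, 0)), "undefined")
  expect_error(mortality_rate(c(50, 20, 30)), "non-increasing")
  expect_error(mortality_rate(c(0, 0)), "positive")
})

test_that("growth is the difference in mean standard length", {
  expect_equal(growth(c(6, 6.2), c(7.5, 7.7)), 1.5)
  expect_equal(growth(c(5, 6, 7), c(5, 6, 7)), 0)
  ## invariant to sample order
  d0 <- rnorm(10, 6); d14 <- rnorm(10, 7.5)
  expect_equal(growth(d0, d14), growth(rev(d0), sample(d14)))
  expect_error(growth(numeric(0), 1), "non-empty")
})

test_that("relative survival arithmetic matches the exponential model", {
  ## 0.109/day per pH unit * 0.1 unit * 20 days
  expect_equal(100 * (1 - relative_survival(0.109 * 0.1, 20)), 19.6,
               tolerance = 0.005)
  ## 0.0126/day excess mortality over the 14-day experiment
  expect_equal(100 * (1 - relative_survival(0.0126, 14)), 16,
               tolerance = 0.02)
  expect_equal(relative_survival(0, 10), 1)
  ## monotone decreasing in both arguments, value in (0, 1]
  dm <- seq(0, 0.2, 0.04)
  v <- relative_survival(dm, 14)
  expect_true(all(diff(v) < 0), all(v > 0), all(v <= 1))
  expect_true(all(diff(relative_survival(0.05, 0:20)) < 0))
})

test_that("paired block test reproduces classical t-test results", {
  set.seed(1)
  amb <- rnorm(16, 0.05, 0.02)
  acid <- amb + rnorm(16, 0.01, 0.02)
  res <- paired_block_test(amb, acid)
  oracle <- t.test(acid, amb, paired = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p_value, oracle$p.value)
  expect_equal(res$mean_difference, unname(oracle$estimate))
  ## swapping treatments negates t, leaves p unchanged
  swap <- paired_block_test(acid, amb)
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
  ## identical vectors: zero difference (t is 0/0, p treated as no evidence)
  same <- paired_block_test(amb, amb)
  expect_equal(same$mean_difference, 0)
  expect_error(paired_block_test(1:3, 1:4), "equal length")
  expect_error(paired_block_test(1, 2), "at least 2")
})

test_that("two-sided p-values from t statistics match printed values", {
  expect_equal(t_test_pvalue(2.36, 15), 0.032, tolerance = 0.01)
  expect_equal(t_test_pvalue(0.283, 15), 0.781, tolerance = 0.01)
  expect_equal(t_test_pvalue(0, 10), 1)
})

test_that("block means aggregate tanks within block and treatment", {
  d <- generate_breeding_design(design_spec(n_blocks = 4, seed = 3))
  tt <- simulate_trait_values(d$pedigree, d$tanks, default_truth(), seed = 4)
  bm <- block_means(tt, "mortality")
  expect_equal(nrow(bm), 4 * 2)
  ## hand-check one cell
  sel <- tt$block == bm$block[1] & tt$treatment == "ambient"
  expect_equal(bm$mean[bm$block == bm$block[1] & bm$treatment == "ambient"],
               mean(tt$mortality_ambient[sel]))
  ## dropping one block's acidified tanks must error and name the block
  tt2 <- tt[!(tt$block == "block02" & tt$treatment == "acidified"), ]
  expect_error(block_means(tt2, "mortality"), "block02")
})

test_that("trait table estimation recovers per-tank rates from raw series", {
  spec <- design_spec(n_blocks = 4, seed = 8)
  ds <- simulate_dataset(spec)
  tt <- build_trait_table(ds$tanks, ds$counts, ds$lengths)
  expect_s3_class(tt, "trait_table")
  expect_equal(nrow(tt), nrow(ds$tanks))
  ## each tank observes exactly the two traits of its own treatment
  obs <- as.matrix(tt[paste0("obs_", c("mortality_ambient",
                                       "mortality_acidified",
                                       "growth_ambient",
                                       "growth_acidified"))])
  expect_true(all(rowSums(obs) == 2))
  amb <- tt$treatment == "ambient"
  expect_true(all(obs[amb, c(1, 3)]) && !any(obs[amb, c(2, 4)]))
  expect_true(all(is.na(tt$mortality_ambient[!amb])))
  ## estimates correlate strongly with the latent truth
  lat <- ds$traits
  ok <- amb & lat$mortality_ambient > 0.005
  expect_gt(cor(tt$mortality_ambient[ok], lat$mortality_ambient[ok]), 0.7)
})
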