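test_that("added mortality subtracts the experiment's ambient mean", {
  meta <- data.frame(
    study = "s1", species = "sp1",
    experiment_id = c("e1", "e1", "e1", "e2", "e2"),
    treatment = c("ambient", "ambient", "acidified", "ambient", "acidified"),
    pco2_uatm = c(450, 450, 1500, 400, 1200),
    ph_nbs = c(8.1, 8.1, 7.6, 8.1, 7.7),
    duration_days = 20,
    daily_mortality = c(0.02, 0.02, 0.05, 0.1, 0.13),
    stringsAsFactors = FALSE)
  am <- added_mortality(meta)
  expect_equal(am$added_mortality[am$experiment_id == "e1" &
                                    am$treatment == "acidified"], 0.03)
  ## ambient replicates average to zero within each experiment
  agg <- tapply(am$added_mortality[am$treatment == "ambient"],
                am$experiment_id[am$treatment == "ambient"], mean)
  expect_equal(as.numeric(agg), c(0, 0))
  ## translation invariance within an experiment
  meta2 <- meta
  meta2$daily_mortality[meta2$experiment_id == "e1"] <-
    meta2$daily_mortality[meta2$experiment_id == "e1"] + 0.5
  am2 <- added_mortality(meta2)
  expect_equal(am2$added_mortality, am$added_mortality)
  ## shuffling experiment order leaves values unchanged (per row)
  shuf <- meta[c(4, 1, 5, 2, 3), ]
  am3 <- added_mortality(shuf)
  key <- function(d) d[order(d$experiment_id, d$pco2_uatm,
                             d$daily_mortality), "added_mortality"]
  expect_equal(key(am3), key(am))
  ## missing ambient control errors
  expect_error(added_mortality(meta[meta$treatment == "acidified", ]),
               "no ambient replicate")
})

test_that("sensitivity slopes match a constructed two-point case", {
  meta <- data.frame(
    study = "s", species = "sp", experiment_id = "e",
    treatment = c("ambient", "acidified"),
    pco2_uatm = c(400, 1400), ph_nbs = c(8.1, 7.6), duration_days = 20,
    daily_mortality = c(0, 0.0297), stringsAsFactors = FALSE)
  sl <- sensitivity_slopes(meta)
  expect_equal(sl$per_pco2, 2.97e-5, tolerance = 1e-12)
  ## pH slope sign convention: mortality increase per unit pH decrease
  expect_equal(sl$per_ph_decrease, 0.0297 / 0.5, tolerance = 1e-12)
  ## constant added mortality: both slopes zero
  meta0 <- meta
  meta0$daily_mortality <- c(0.05, 0.05)
  sl0 <- sensitivity_slopes(meta0)
  expect_equal(sl0$per_pco2, 0)
  expect_equal(sl0$per_ph_decrease, 0)
})

test_that("slopes recover a known generating relationship", {
  slope <- 3e-5
  meta <- synthetic_meta(slope = slope, noise = 0.002, seed = 11)
  fit <- sensitivity_slopes(meta)
  ## pooled OLS within 3 SE of truth
  am <- added_mortality(meta)
  x <- am$pco2_uatm
  se <- 0.002 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$per_pco2 - slope), 3 * se)
  ## species-averaged variant close to pooled here (balanced design)
  fit2 <- sensitivity_slopes(meta, pooled = FALSE)
  expect_equal(fit2$per_pco2, fit$per_pco2, tolerance = 0.3 * slope)
  ## noiseless: exact
  clean <- synthetic_meta(slope = slope, noise = 0)
  expect_equal(sensitivity_slopes(clean)$per_pco2, slope, tolerance = 1e-10)
})

test_that("survival projections follow the exponential model", {
  expect_equal(project_survival_curve(0.109, 0.005, 0, 20), 1)
  ## 0.1 pH-unit decrease sustained over 20 days: ~19.5% decrease
  s <- project_survival_curve(0.109, 0.1, 1, 20)
  expect_equal(100 * (1 - s), 19.6, tolerance = 0.05)
  ## monotone decreasing in horizon
  ss <- vapply(0:50, function(yr)
    project_survival_curve(2.97e-5, 6, yr, 20), numeric(1))
  expect_true(all(diff(ss) < 0))
  expect_true(all(ss > 0 & ss <= 1))
})

test_that("correlation test matches the printed size-tolerance analysis", {
  ## r = 0.294 with 12 df gives the reported weak evidence
  r <- 0.294; df <- 12
  tstat <- r * sqrt(df / (1 - r^2))
  expect_equal(t_test_pvalue(tstat, df), 0.31, tolerance = 0.02)
  ## construct data with an exact sample correlation and check the test
  set.seed(12)
  n <- 14
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  xs <- scale(x)[, 1]
  y <- r * xs + sqrt(1 - r^2) * scale(e)[, 1]
  res <- correlation_test(xs, y)
  expect_equal(res$r, r, tolerance = 1e-10)
  expect_equal(res$df, n - 2)
  oracle <- cor.test(xs, y)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  ## collinear data
  res2 <- correlation_test(1:10, 2 * (1:10) + 3)
  expect_equal(res2$r, 1)
  expect_equal(res2$p_value, 0)
  expect_error(correlation_test(rep(1, 5), 1:5), "zero variance")
  expect_error(correlation_test(1:2, 1:2), ">= 3")
})

test_that("null p-values of the correlation test are uniform", {
  set.seed(13)
  p <- replicate(1000, {
    correlation_test(rnorm(14), rnorm(14))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("meta table reader enforces the schema", {
  meta <- synthetic_meta()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(meta, path, row.names = FALSE)
  rd <- read_meta(path)
  expect_equal(nrow(rd), nrow(meta))
  bad <- meta[setdiff(names(meta), "ph_nbs")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_meta(path), "ph_nbs")
})
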