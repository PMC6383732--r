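#' Simulate latent tank trait values
#'
#' Draws, for every tank, a latent 4-vector
#' `y = mu + a + m + b + e` where `a` is the tank pseudo-individual's
#' breeding value under the additive model over the pedigree (founders
#' `N(0, G)`, offspring `0.5 (a_sire + a_dam)` plus mendelian sampling
#' `N(0, G/2)` for non-inbred parents), `m` is shared by tanks with the
#' same dam, `b` by tanks in the same block, and `e` is independent per
#' tank. Only the two traits matching the tank's treatment are flagged
#' observed.
#'
#' @param ped a [pedigree] containing every tank pseudo-individual.
#' @param tanks tank data frame from [generate_breeding_design()].
#' @param truth a [truth_params].
#' @param seed integer seed.
#' @return a `trait_table` data frame: one row per tank with columns
#'   `tank_id`, `individual`, `dam`, `block`, `treatment`, the four latent
#'   trait values, and logical `obs_*` mask columns.
#' @export
simulate_trait_values <- function(ped, tanks, truth, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), inherits(truth, "truth_params"))
  if (!all(tanks$tank_id %in% ped$id)) {
    stop("tanks reference individuals missing from the pedigree")
  }
  set.seed(seed)
  tn <- truth$trait_names
  chol_or_zero <- function(V) {
    ## PSD factor L with V = L L' (eigendecomposition handles singular V)
    e <- eigen((V + t(V)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(1, max(abs(V)))) {
      stop("truth matrices must be positive semidefinite")
    }
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 4)
  }
  Lg <- chol_or_zero(truth$G)
  Lm <- chol_or_zero(truth$M)
  Lb <- chol_or_zero(truth$B)
  Lr <- chol_or_zero(truth$R)
  draw <- function(L, n) t(L %*% matrix(rnorm(4 * n), 4, n))

  ## breeding values by pedigree recursion (parents precede offspring)
  q <- length(ped$id)
  avals <- matrix(0, q, 4)
  founder <- is.na(ped$sire) & is.na(ped$dam)
  avals[founder, ] <- draw(Lg, sum(founder))
  mend <- draw(Lg / sqrt(2), q)  # mendelian-sampling deviations
  for (j in which(!founder)) {
    ps <- if (!is.na(ped$sire[j])) avals[ped$sire[j], ] else 0
    pd <- if (!is.na(ped$dam[j])) avals[ped$dam[j], ] else 0
    avals[j, ] <- 0.5 * (ps + pd) + mend[j, ]
  }

  dams <- unique(tanks$dam_id)
  blocks <- unique(tanks$block)
  mvals <- draw(Lm, length(dams))
  bvals <- draw(Lb, length(blocks))
  evals <- draw(Lr, nrow(tanks))

  idx_i <- match(tanks$tank_id, ped$id)
  idx_d <- match(tanks$dam_id, dams)
  idx_b <- match(tanks$block, blocks)
  y <- matrix(rep(truth$mu, each = nrow(tanks)), nrow(tanks), 4) +
    avals[idx_i, , drop = FALSE] + mvals[idx_d, , drop = FALSE] +
    bvals[idx_b, , drop = FALSE] + evals
  colnames(y) <- tn

  amb <- tanks$treatment == "ambient"
  obs <- cbind(amb, !amb, amb, !amb)
  colnames(obs) <- paste0("obs_", tn)
  out <- data.frame(tank_id = tanks$tank_id, individual = tanks$tank_id,
                    dam = tanks$dam_id, block = tanks$block,
                    treatment = tanks$treatment, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(y), as.data.frame(obs))
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate a daily survivor series
#'
#' Discretizes continuous exponential mortality at rate `m` per day as
#' daily binomial thinning with survival probability `exp(-m)`, so the
#' expected count at day t is `n0 * exp(-m * t)` and the log-survivor
#' regression estimator of `m` is asymptotically unbiased.
#'
#' @param m daily mortality rate (>= 0).
#' @param n0 initial count (> 0).
#' @param days number of days.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return integer vector of length `days + 1` (day 0 through `days`),
#'   non-increasing, starting at `n0`.
#' @export
simulate_daily_counts <- function(m, n0, days, seed = NULL) {
  if (!is.finite(m) || m < 0) stop("mortality rate m must be >= 0")
  stopifnot(n0 > 0, days >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- integer(days + 1)
  n[1] <- as.integer(n0)
  p <- exp(-m)
  for (t in seq_len(days)) {
    n[t + 1] <- rbinom(1, n[t], p)
  }
  n
}

#' Simulate standard-length samples
#'
#' Two samples of `n` lengths with population mean difference equal to
#' `growth`: day-0 lengths centered at `base_len`, final lengths at
#' `base_len + growth`, both with gaussian measurement/individual noise.
#'
#' @param growth true change in mean standard length (mm).
#' @param base_len mean day-0 standard length (mm).
#' @param n larvae sampled per time point (> 0).
#' @param noise_sd standard deviation of individual lengths (mm, >= 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with numeric vectors `day0` and `day14`.
#' @export
simulate_lengths <- function(growth, base_len = 6, n = 10, noise_sd = 0.2,
                             seed = NULL) {
  stopifnot(n > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  list(day0 = base_len + rnorm(n, 0, noise_sd),
       day14 = base_len + growth + rnorm(n, 0, noise_sd))
}

#' Simulate a complete dataset
#'
#' Runs the full generative chain: breeding design, latent trait values,
#' daily survivor counts per tank (from the tank's treatment-specific
#' latent mortality rate, truncated at zero since a latent gaussian rate
#' can be negative), and day-0 / final standard-length samples (from the
#' latent growth trait).
#'
#' @param spec a [design_spec].
#' @param truth a [truth_params].
#' @param base_len mean day-0 length (mm).
#' @param length_noise_sd individual length standard deviation (mm).
#' @return list with `pedigree`, `tanks`, `traits` (latent trait table),
#'   `counts` (data frame `tank_id, day, n_alive`), `lengths` (data frame
#'   `tank_id, day, length_mm`) and `truth`.
#' @export
simulate_dataset <- function(spec, truth = default_truth(), base_len = 6,
                             length_noise_sd = 0.2) {
  design <- generate_breeding_design(spec)
  traits <- simulate_trait_values(design$pedigree, design$tanks, truth,
                                  seed = spec$seed + 1L)
  set.seed(spec$seed + 2L)
  counts <- vector("list", nrow(design$tanks))
  lengths <- vector("list", nrow(design$tanks))
  for (i in seq_len(nrow(design$tanks))) {
    trt <- design$tanks$treatment[i]
    m <- traits[[paste0("mortality_", trt)]][i]
    g <- traits[[paste0("growth_", trt)]][i]
    series <- simulate_daily_counts(max(m, 0), spec$larvae_per_tank,
                                    spec$duration_days)
    counts[[i]] <- data.frame(tank_id = design$tanks$tank_id[i],
                              day = 0:spec$duration_days, n_alive = series,
                              stringsAsFactors = FALSE)
    ls <- simulate_lengths(g, base_len, spec$lengths_sampled_per_tank,
                           length_noise_sd)
    lengths[[i]] <- data.frame(
      tank_id = design$tanks$tank_id[i],
      day = rep(c(0L, spec$duration_days),
                each = spec$lengths_sampled_per_tank),
      length_mm = c(ls$day0, ls$day14), stringsAsFactors = FALSE)
  }
  list(pedigree = design$pedigree, tanks = design$tanks, traits = traits,
       counts = do.call(rbind, counts), lengths = do.call(rbind, lengths),
       truth = truth)
}

#' Write a simulated dataset to CSV files
#'
#' Emits `pedigree.csv`, `tanks.csv`, `counts.csv`, `lengths.csv` and a
#' `truth.json` parameter dump (for parameter-recovery tests) into `dir`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.csv"))
  write.csv(dataset$tanks, file.path(dir, "tanks.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$counts, file.path(dir, "counts.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$lengths, file.path(dir, "lengths.csv"),
            row.names = FALSE, quote = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(
    list(mu = tr$mu, G = tr$G, M = tr$M, B = tr$B, R = tr$R,
         trait_names = tr$trait_names),
    file.path(dir, "truth.json"), digits = NA, matrix = "rowmajor")
  invisible(dir)
}
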