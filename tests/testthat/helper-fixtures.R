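# Shared fixtures built in code.

# trio: sire, dam, two full-sib offspring
trio_pedigree <- function() {
  pedigree(c("s", "d", "o1", "o2"), c(NA, NA, "s", "s"), c(NA, NA, "d", "d"))
}

# the usual two-set spawning-event design (one block, 18 families)
two_set_design <- function(seed = 1) {
  generate_breeding_design(design_spec(n_blocks = 1, sets_per_block = 2,
                                       seed = seed))
}

# small complete-data trait table + model spec for fast sampler tests
small_fitted_problem <- function(seed = 5, complete = FALSE, n_blocks = 6) {
  spec <- design_spec(n_blocks = n_blocks, sets_per_block = 2, seed = seed)
  d <- generate_breeding_design(spec)
  tt <- simulate_trait_values(d$pedigree, d$tanks, default_truth(),
                              seed = seed + 1)
  if (complete) {
    for (t in c("mortality_ambient", "mortality_acidified",
                "growth_ambient", "growth_acidified")) {
      tt[[paste0("obs_", t)]] <- TRUE
    }
  }
  list(design = d, traits = tt, model = model_spec(tt, d$pedigree),
       prior = prior_from_data(tt))
}

# G matrix for larval mortality in the two environments, as estimated by
# the animal model (used in the worked selection-response example)
mortality_G <- function() {
  matrix(c(2.48e-4, 2.10e-4, 2.10e-4, 7.23e-4), 2, 2,
         dimnames = list(c("ambient", "acidified"),
                         c("ambient", "acidified")))
}

# small synthetic meta-analysis table with a known linear added-mortality
# relationship (slope per uatm), ambient at pco2_0
synthetic_meta <- function(slope = 3e-5, pco2_0 = 450, n_exp = 8,
                           reps = 3, noise = 0, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (e in seq_len(n_exp)) {
    base <- runif(1, 0.02, 0.12)
    pco2 <- c(pco2_0, pco2_0 + seq(300, 1200, length.out = reps))
    trt <- c("ambient", rep("acidified", reps))
    for (i in seq_along(pco2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        study = paste0("study", e), species = paste0("sp", (e %% 4) + 1),
        experiment_id = paste0("exp", e), treatment = trt[i],
        pco2_uatm = pco2[i],
        ph_nbs = 8.1 - (pco2[i] - pco2_0) / 1500,
        duration_days = 20,
        daily_mortality = base + slope * (pco2[i] - pco2_0) +
          rnorm(1, 0, noise),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
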