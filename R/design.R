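#' Breeding-design specification
#'
#' Describes a crossed breeding design: replicated temporal blocks
#' (spawning events), each containing one or two full-factorial sets of
#' sires crossed with dams, with larvae from a random subset of the
#' resulting full-sib families reared in duplicate tanks under the two
#' seawater treatments (ambient and acidified). Defaults emulate the
#' grunion experiment: 16 blocks, two 3 x 3 sets per block, at most 12
#' family-replicates per treatment per block, 50 larvae per tank, a 14-day
#' rearing period, and 10 larvae measured for length per tank.
#'
#' @param n_blocks number of temporal blocks.
#' @param sets_per_block full-factorial sets per block (1 or 2).
#' @param sires_per_set,dams_per_set parents per set.
#' @param max_tanks_per_treatment_per_block rearing capacity per treatment
#'   within a block.
#' @param duplicate_family_fraction fraction of reared families given a
#'   second tank in each treatment, in `[0, 1]`.
#' @param larvae_per_tank initial stocking per tank.
#' @param duration_days rearing period (days).
#' @param lengths_sampled_per_tank larvae measured for standard length per
#'   tank at day 0 and at the end.
#' @param seed integer seed used by [generate_breeding_design()].
#' @return an object of class `"design_spec"` (a validated list).
#' @export
design_spec <- function(n_blocks = 16,
                        sets_per_block = 2,
                        sires_per_set = 3,
                        dams_per_set = 3,
                        max_tanks_per_treatment_per_block = 12,
                        duplicate_family_fraction = 0.2,
                        larvae_per_tank = 50,
                        duration_days = 14,
                        lengths_sampled_per_tank = 10,
                        seed = 1) {
  spec <- list(n_blocks = n_blocks, sets_per_block = sets_per_block,
               sires_per_set = sires_per_set, dams_per_set = dams_per_set,
               max_tanks_per_treatment_per_block = max_tanks_per_treatment_per_block,
               duplicate_family_fraction = duplicate_family_fraction,
               larvae_per_tank = larvae_per_tank,
               duration_days = duration_days,
               lengths_sampled_per_tank = lengths_sampled_per_tank,
               seed = seed)
  counts <- spec[c("n_blocks", "sets_per_block", "sires_per_set",
                   "dams_per_set", "max_tanks_per_treatment_per_block",
                   "larvae_per_tank", "duration_days",
                   "lengths_sampled_per_tank")]
  if (any(vapply(counts, function(x) length(x) != 1 || !is.finite(x) || x < 1 ||
                   x != round(x), logical(1)))) {
    stop("all design counts must be positive integers")
  }
  if (!is.finite(duplicate_family_fraction) ||
      duplicate_family_fraction < 0 || duplicate_family_fraction > 1) {
    stop("duplicate_family_fraction must be in [0, 1]")
  }
  if (!sets_per_block %in% c(1, 2)) {
    stop("sets_per_block must be 1 or 2")
  }
  structure(spec, class = "design_spec")
}

#' Ground-truth simulation parameters
#'
#' Trait means plus the four 4 x 4 (co)variance components that generate
#' phenotypes: additive genetic (`G`), maternal (`M`), block (`B`) and
#' residual / among-tank (`R`). The modeled phenotypic covariance is their
#' sum, `P = G + M + B + R`. Trait order throughout the package is
#' mortality (ambient), mortality (acidified), growth (ambient), growth
#' (acidified); mortality is a daily rate, growth is mm over the rearing
#' period.
#'
#' @param mu numeric 4-vector of trait means.
#' @param G,M,B,R symmetric positive-semidefinite 4 x 4 matrices.
#' @return an object of class `"truth_params"`.
#' @export
truth_params <- function(mu, G, M, B, R) {
  stopifnot(length(mu) == 4)
  comps <- list(G = G, M = M, B = B, R = R)
  for (nm in names(comps)) {
    V <- comps[[nm]]
    if (!is.matrix(V) || !all(dim(V) == 4)) stop(nm, " must be a 4x4 matrix")
    if (max(abs(V - t(V))) > 1e-8) stop(nm, " must be symmetric")
    if (min(eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(1, max(abs(V)))) {
      stop(nm, " must be positive semidefinite")
    }
  }
  structure(c(list(mu = as.numeric(mu)), comps,
              list(trait_names = oaq_trait_names())),
            class = "truth_params")
}

oaq_trait_names <- function() {
  c("mortality_ambient", "mortality_acidified",
    "growth_ambient", "growth_acidified")
}

#' Default ground-truth parameters
#'
#' A realistic parameterization for testing: daily mortality means near the
#' observed scale (0.05/day ambient, raised under acidification), 1.5 mm
#' growth, and components built from target variance proportions
#' (heritability, maternal, block, residual) and within-trait-pair
#' correlations.
#'
#' @param p_total numeric 4-vector of total phenotypic variances.
#' @param h2 numeric 4-vector of heritabilities (additive proportions).
#' @param m_prop,b_prop numeric 4-vectors of maternal and block proportions.
#' @param r_G,r_M,r_B cross-environment correlations applied within the
#'   mortality pair and within the growth pair for G, M and B.
#' @param mu trait means.
#' @return a [truth_params] object. Residual proportion is the remainder
#'   `1 - h2 - m_prop - b_prop` (must be positive); R is diagonal.
#' @export
default_truth <- function(p_total = c(2e-3, 3e-3, 0.25, 0.25),
                          h2 = c(0.2, 0.2, 0.1, 0.1),
                          m_prop = rep(0.3, 4),
                          b_prop = rep(0.4, 4),
                          r_G = c(0.45, 0.15),
                          r_M = c(0.8, 0.8),
                          r_B = c(0.5, 0.5),
                          mu = c(0.05, 0.065, 1.5, 1.5)) {
  e_prop <- 1 - h2 - m_prop - b_prop
  if (any(e_prop <= 0)) stop("proportions leave no residual variance")
  pair_cov <- function(v, r) {
    ## block-diagonal over the two trait pairs (1,2) and (3,4)
    V <- diag(v)
    V[1, 2] <- V[2, 1] <- r[1] * sqrt(v[1] * v[2])
    V[3, 4] <- V[4, 3] <- r[2] * sqrt(v[3] * v[4])
    V
  }
  truth_params(mu = mu,
               G = pair_cov(h2 * p_total, r_G),
               M = pair_cov(m_prop * p_total, r_M),
               B = pair_cov(b_prop * p_total, r_B),
               R = diag(e_prop * p_total))
}

#' Generate a crossed breeding design
#'
#' Builds the pedigree (founder sires and dams per set, plus one
#' pseudo-individual per rearing tank whose parents are the family's sire
#' and dam) and the tank layout. Within each block, every set crosses each
#' sire with each dam (full factorial), a random subset of the resulting
#' full-sib families is chosen for rearing subject to the per-treatment
#' tank capacity, each chosen family gets one tank in each treatment, and a
#' `duplicate_family_fraction` of chosen families receive a second tank per
#' treatment. Replicate tanks of one family are distinct full sibs
#' (additive relatedness 0.5).
#'
#' @param spec a [design_spec].
#' @return a list with elements `pedigree` (a [pedigree]), `tanks` (a
#'   data frame with columns `tank_id`, `family_id`, `sire_id`, `dam_id`,
#'   `block`, `treatment`) and `families` (all crossed families with a
#'   `reared` flag).
#' @export
generate_breeding_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$max_tanks_per_treatment_per_block < 1) {
    stop("capacity must allow at least one family (2 tanks, one per treatment)")
  }
  set.seed(spec$seed)
  founders <- list()
  tanks <- list()
  families <- list()
  for (b in seq_len(spec$n_blocks)) {
    fams <- list()
    for (s in seq_len(spec$sets_per_block)) {
      sires <- sprintf("B%02dS%dM%d", b, s, seq_len(spec$sires_per_set))
      dams <- sprintf("B%02dS%dF%d", b, s, seq_len(spec$dams_per_set))
      founders[[length(founders) + 1L]] <- c(sires, dams)
      for (si in sires) for (di in dams) {
        fams[[length(fams) + 1L]] <- list(sire = si, dam = di)
      }
    }
    cap <- spec$max_tanks_per_treatment_per_block
    dupf <- spec$duplicate_family_fraction
    n_fam <- length(fams)
    ## choose as many families as capacity allows once duplicates are added
    n_sel <- min(n_fam, max(1L, floor(cap / (1 + dupf))))
    n_dup <- min(cap - n_sel, round(dupf * n_sel))
    sel <- sample.int(n_fam, n_sel)
    dup <- if (n_dup > 0) sample(sel, n_dup) else integer(0)
    reps <- c(sel, dup)  # family index per family-replicate
    for (f in seq_len(n_fam)) {
      fam <- fams[[f]]
      families[[length(families) + 1L]] <- data.frame(
        family_id = sprintf("B%02d_%s_x_%s", b, fam$sire, fam$dam),
        sire_id = fam$sire, dam_id = fam$dam,
        block = sprintf("block%02d", b), reared = f %in% sel,
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(reps)) {
      fam <- fams[[reps[k]]]
      fam_id <- sprintf("B%02d_%s_x_%s", b, fam$sire, fam$dam)
      for (trt in c("ambient", "acidified")) {
        tanks[[length(tanks) + 1L]] <- data.frame(
          tank_id = NA_character_, family_id = fam_id,
          sire_id = fam$sire, dam_id = fam$dam,
          block = sprintf("block%02d", b), treatment = trt,
          stringsAsFactors = FALSE)
      }
    }
  }
  tanks <- do.call(rbind, tanks)
  tanks$tank_id <- sprintf("T%04d", seq_len(nrow(tanks)))
  founders <- unlist(founders)
  ped <- pedigree(c(founders, tanks$tank_id),
                  c(rep(NA, length(founders)), tanks$sire_id),
                  c(rep(NA, length(founders)), tanks$dam_id))
  list(pedigree = ped, tanks = tanks, families = do.call(rbind, families))
}
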