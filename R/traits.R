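#' Daily mortality rate from a survivor series
#'
#' The daily mortality rate is the negative of the slope of an ordinary
#' least-squares regression of the natural logarithm of the number of
#' surviving larvae on time (days). Days with zero survivors are excluded
#' (the series is truncated at the last positive count); day 0 — the known
#' initial stocking — is included.
#'
#' @param counts integer survivor series, `counts[1]` at day 0.
#' @param days optional day vector matching `counts`; defaults to
#'   `0:(length(counts) - 1)`.
#' @return daily mortality rate (per day).
#' @examples
#' mortality_rate(round(50 * exp(-0.1 * 0:14)))  # ~ 0.1
#' @export
mortality_rate <- function(counts, days = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(days))
  if (length(counts) && counts[1] <= 0) stop("initial count must be positive")
  if (any(diff(counts) > 0)) stop("survivor series must be non-increasing")
  keep <- counts > 0
  if (sum(keep) < 2) {
    stop("undefined mortality rate: fewer than 2 days with survivors")
  }
  x <- days[keep]
  y <- log(counts[keep])
  -sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Growth as change in mean standard length
#'
#' @param day0_lengths,day14_lengths numeric length samples (mm) at the
#'   start and end of the rearing period.
#' @return `mean(day14_lengths) - mean(day0_lengths)` (mm).
#' @export
growth <- function(day0_lengths, day14_lengths) {
  if (!length(day0_lengths) || !length(day14_lengths)) {
    stop("length samples must be non-empty")
  }
  mean(day14_lengths) - mean(day0_lengths)
}

#' Relative survival under added mortality
#'
#' Under exponential mortality, an added daily mortality `delta_m`
#' sustained for `days` days multiplies survival by
#' `exp(-delta_m * days)`. The percentage decrease in relative survival is
#' `100 * (1 - relative_survival(delta_m, days))`.
#'
#' @param delta_m added daily mortality rate (per day).
#' @param days exposure duration (days, >= 0).
#' @return relative survival in `(0, 1]` for `delta_m >= 0`.
#' @examples
#' 100 * (1 - relative_survival(0.109 * 0.1, 20))  # ~19.6% decrease
#' @export
relative_survival <- function(delta_m, days) {
  stopifnot(days >= 0)
  exp(-delta_m * days)
}

#' Paired t test over block means
#'
#' Classical paired t test treating blocks as replicates: for differences
#' `d = acidified - ambient`, `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1` and a two-sided p-value.
#'
#' @param ambient_by_block,acidified_by_block equal-length numeric vectors
#'   of per-block means (length >= 2).
#' @return list with `mean_difference` (acidified minus ambient),
#'   `statistic`, `df`, `p_value`.
#' @export
paired_block_test <- function(ambient_by_block, acidified_by_block) {
  if (length(ambient_by_block) != length(acidified_by_block)) {
    stop("paired vectors must have equal length")
  }
  n <- length(ambient_by_block)
  if (n < 2) stop("need at least 2 blocks")
  d <- acidified_by_block - ambient_by_block
  sdd <- sd(d)
  tstat <- if (sdd == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sdd / sqrt(n))
  }
  list(mean_difference = mean(d), statistic = tstat, df = n - 1,
       p_value = t_test_pvalue(tstat, n - 1))
}

#' Two-sided p-value from a t statistic
#'
#' @param statistic t statistic.
#' @param df degrees of freedom.
#' @return two-sided tail probability.
#' @examples
#' t_test_pvalue(2.36, 15)  # 0.032
#' @export
t_test_pvalue <- function(statistic, df) {
  2 * pt(-abs(statistic), df)
}

#' Per-block, per-treatment means of a trait
#'
#' Averages, within each block-by-treatment cell, the value each tank
#' expresses for `trait` in its own treatment (e.g. ambient tanks
#' contribute `mortality_ambient`, acidified tanks
#' `mortality_acidified`). These are the block replicates used by the
#' paired treatment contrast ([paired_block_test()]).
#'
#' @param trait_table a trait table (see [build_trait_table()]).
#' @param trait `"mortality"` or `"growth"`.
#' @return data frame `block, treatment, mean`; errors if a block lacks
#'   tanks in either treatment.
#' @export
block_means <- function(trait_table, trait = c("mortality", "growth")) {
  trait <- match.arg(trait)
  val <- ifelse(trait_table$treatment == "ambient",
                trait_table[[paste0(trait, "_ambient")]],
                trait_table[[paste0(trait, "_acidified")]])
  if (any(is.na(val))) stop("trait values missing for some tanks")
  agg <- aggregate(val, by = list(block = trait_table$block,
                                  treatment = trait_table$treatment),
                   FUN = mean)
  names(agg)[3] <- "mean"
  cnt <- table(agg$block)
  missing <- names(cnt)[cnt < 2]
  if (length(missing)) {
    stop("blocks missing a treatment: ", paste(missing, collapse = ", "))
  }
  agg[order(agg$block, agg$treatment), , drop = FALSE]
}

#' Build a per-tank trait table from raw observations
#'
#' Estimates the tank's two treatment-specific traits — daily mortality
#' rate from the survivor series ([mortality_rate()]) and growth from the
#' length samples ([growth()]) — and lays them out as the four analysis
#' traits with the structural observed/missing mask (each tank observes
#' exactly the two traits of its own treatment).
#'
#' @param tanks tank data frame (`tank_id`, `family_id`, `sire_id`,
#'   `dam_id`, `block`, `treatment`).
#' @param counts data frame `tank_id, day, n_alive`.
#' @param lengths data frame `tank_id, day, length_mm` with day 0 and a
#'   single final day per tank.
#' @return a `trait_table` data frame as in [simulate_trait_values()],
#'   with unobserved trait cells `NA`.
#' @export
build_trait_table <- function(tanks, counts, lengths) {
  stopifnot(all(tanks$treatment %in% c("ambient", "acidified")))
  tn <- oaq_trait_names()
  n <- nrow(tanks)
  y <- matrix(NA_real_, n, 4, dimnames = list(NULL, tn))
  for (i in seq_len(n)) {
    id <- tanks$tank_id[i]
    trt <- tanks$treatment[i]
    cc <- counts[counts$tank_id == id, , drop = FALSE]
    cc <- cc[order(cc$day), , drop = FALSE]
    if (!nrow(cc)) stop("no survivor counts for tank ", id)
    ll <- lengths[lengths$tank_id == id, , drop = FALSE]
    if (!nrow(ll)) stop("no length samples for tank ", id)
    d0 <- ll$length_mm[ll$day == 0]
    d1 <- ll$length_mm[ll$day == max(ll$day)]
    y[i, paste0("mortality_", trt)] <- mortality_rate(cc$n_alive, cc$day)
    y[i, paste0("growth_", trt)] <- growth(d0, d1)
  }
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
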