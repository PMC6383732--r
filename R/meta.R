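#' Read a compiled meta-analysis table
#'
#' Expected columns: `study`, `species`, `experiment_id`, `treatment`,
#' `pco2_uatm`, `ph_nbs`, `duration_days`, `daily_mortality`, and
#' optionally `larval_size_mm`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @examples
#' meta <- read_meta(system.file("extdata", "meta_synthetic.csv",
#'                               package = "oaquant"))
#' sensitivity_slopes(meta)
#' @export
read_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("study", "species", "experiment_id", "treatment",
                "pco2_uatm", "ph_nbs", "duration_days", "daily_mortality")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("meta table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Acidification-added daily mortality
#'
#' Within each experiment, subtracts the mean daily mortality of the
#' ambient replicates from every replicate's daily mortality. This parses
#' out the component of mortality attributable to the pCO2/pH manipulation
#' while removing natural among-species and among-study differences in
#' baseline mortality; ambient replicates average to zero by construction.
#'
#' @param meta a meta-analysis table (see [read_meta()]); `treatment` must
#'   contain `"ambient"` labels marking control replicates.
#' @return `meta` with an `added_mortality` column.
#' @export
added_mortality <- function(meta) {
  out <- lapply(split(meta, meta$experiment_id), function(exp) {
    amb <- exp$daily_mortality[exp$treatment == "ambient"]
    if (!length(amb)) {
      stop("experiment ", exp$experiment_id[1], " has no ambient replicate")
    }
    exp$added_mortality <- exp$daily_mortality - mean(amb)
    exp
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sensitivity of larval mortality to pCO2 and pH
#'
#' Ordinary least-squares regressions of acidification-added daily
#' mortality on pCO2 (slope per microatmosphere increase) and, separately,
#' on pH (reported as the mortality increase per unit pH *decrease*, i.e.
#' the negated regression slope). `pooled = TRUE` fits one regression
#' across all replicates; `pooled = FALSE` fits per-species slopes and
#' averages them.
#'
#' @param meta a meta-analysis table.
#' @param pooled logical; pooled OLS (default) or mean of per-species
#'   slopes.
#' @return list with `per_pco2` (per microatm) and `per_ph_decrease`
#'   (per pH unit).
#' @export
sensitivity_slopes <- function(meta, pooled = TRUE) {
  am <- if ("added_mortality" %in% names(meta)) meta else added_mortality(meta)
  slope <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2) stop("degenerate predictor in slope fit")
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  fit <- function(d) {
    c(per_pco2 = slope(d$pco2_uatm, d$added_mortality),
      per_ph_decrease = -slope(d$ph_nbs, d$added_mortality))
  }
  if (pooled) {
    as.list(fit(am))
  } else {
    per_sp <- vapply(split(am, am$species), fit, numeric(2))
    list(per_pco2 = mean(per_sp["per_pco2", ]),
         per_ph_decrease = mean(per_sp["per_ph_decrease", ]))
  }
}

#' Projected relative survival under a changing driver
#'
#' Combines a mortality sensitivity slope (added daily mortality per unit
#' driver change) with a driver trend (units per year) and a larval
#' exposure window: relative survival after `years` is
#' `exp(-slope * rate * years * exposure_days)`.
#'
#' @param slope added daily mortality per unit driver (e.g. 0.109 per pH
#'   unit decrease, or 2.97e-5 per microatm pCO2).
#' @param driver_rate_per_year driver change per year (positive).
#' @param years projection horizon.
#' @param exposure_days larval exposure duration (days).
#' @return relative survival in `(0, 1]`.
#' @export
project_survival_curve <- function(slope, driver_rate_per_year, years,
                                   exposure_days) {
  stopifnot(slope >= 0, driver_rate_per_year >= 0, years >= 0,
            exposure_days >= 0)
  relative_survival(slope * driver_rate_per_year * years, exposure_days)
}

#' Pearson correlation test
#'
#' Pearson r with the classical t test: `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`, two-sided p-value. Used for the larval size versus pH
#' tolerance relationship across species.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return list with `r`, `statistic`, `df`, `p_value`.
#' @export
correlation_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in correlation test")
  r <- cor(x, y)
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, statistic = tstat, df = df,
       p_value = if (is.finite(tstat)) t_test_pvalue(tstat, df) else 0)
}
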