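#' Pipeline run configuration
#'
#' Either simulation mode (`design` + `truth` supplied, data generated on
#' the fly) or data mode (`input_dir` containing `pedigree.csv`,
#' `tanks.csv`, `counts.csv`, `lengths.csv`); the two are mutually
#' exclusive.
#'
#' @param input_dir directory of input CSV tables (data mode).
#' @param design a [design_spec] (simulation mode).
#' @param truth a [truth_params] (simulation mode).
#' @param n_iter,burn_in,thin chain settings.
#' @param seed integer seed for the whole run.
#' @param prior_nu inverse-Wishart degree of belief.
#' @param interval `"hpd"` or `"quantile"`.
#' @param beta optional length-4 selection gradient for the projection
#'   stage.
#' @param output_dir where outputs are written.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(input_dir = NULL, design = NULL, truth = NULL,
                       n_iter = 150000, burn_in = 1000, thin = 80,
                       seed = 1, prior_nu = 0.001,
                       interval = c("hpd", "quantile"), beta = NULL,
                       output_dir = tempfile("oaquant_run")) {
  interval <- match.arg(interval)
  sim_mode <- !is.null(design)
  if (sim_mode && !is.null(input_dir)) {
    stop("simulation mode and data mode are mutually exclusive")
  }
  if (!sim_mode && is.null(input_dir)) {
    stop("supply either input_dir (data mode) or design (simulation mode)")
  }
  if (sim_mode && is.null(truth)) truth <- default_truth()
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1, prior_nu > 0)
  structure(list(input_dir = input_dir, design = design, truth = truth,
                 sim_mode = sim_mode, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed, prior_nu = prior_nu,
                 interval = interval, beta = beta, output_dir = output_dir),
            class = "run_config")
}

#' Validate pipeline input tables
#'
#' Checks table schemas, referential integrity (tanks reference pedigree
#' members; counts and lengths reference tanks), non-increasing survivor
#' series, and the treatment vocabulary (`ambient`/`acidified`).
#'
#' @param dir directory containing `pedigree.csv`, `tanks.csv`,
#'   `counts.csv`, `lengths.csv`.
#' @return data frame of violations (`file`, `location`, `message`);
#'   zero rows when everything is well formed.
#' @export
validate_tables <- function(dir) {
  v <- list()
  note <- function(file, location, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, location = location,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  need <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      note(name, "-", "file missing")
      return(NULL)
    }
    read.csv(path, stringsAsFactors = FALSE)
  }
  check_cols <- function(df, name, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      note(name, "header", paste("missing columns:",
                                 paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  ped <- need("pedigree.csv")
  tanks <- need("tanks.csv")
  counts <- need("counts.csv")
  lengths <- need("lengths.csv")
  ped_ok <- !is.null(ped) && check_cols(ped, "pedigree.csv",
                                        c("id", "sire", "dam"))
  tank_ok <- !is.null(tanks) &&
    check_cols(tanks, "tanks.csv",
               c("tank_id", "family_id", "sire_id", "dam_id", "block",
                 "treatment"))
  if (tank_ok) {
    bad <- !tanks$treatment %in% c("ambient", "acidified")
    for (i in which(bad)) {
      note("tanks.csv", paste("row", i),
           paste("unknown treatment label:", tanks$treatment[i]))
    }
    if (ped_ok) {
      for (i in which(!tanks$tank_id %in% ped$id)) {
        note("tanks.csv", paste("row", i),
             paste("tank_id not in pedigree:", tanks$tank_id[i]))
      }
    }
  }
  if (!is.null(counts) &&
      check_cols(counts, "counts.csv", c("tank_id", "day", "n_alive"))) {
    if (tank_ok) {
      for (id in setdiff(unique(counts$tank_id), tanks$tank_id)) {
        note("counts.csv", paste("tank", id), "tank_id not in tanks.csv")
      }
    }
    for (id in unique(counts$tank_id)) {
      cc <- counts[counts$tank_id == id, ]
      cc <- cc[order(cc$day), ]
      if (any(diff(cc$n_alive) > 0)) {
        note("counts.csv", paste("tank", id),
             "survivor counts increase between days")
      }
    }
  }
  if (!is.null(lengths) &&
      check_cols(lengths, "lengths.csv", c("tank_id", "day", "length_mm")) &&
      tank_ok) {
    for (id in setdiff(unique(lengths$tank_id), tanks$tank_id)) {
      note("lengths.csv", paste("tank", id), "tank_id not in tanks.csv")
    }
  }
  if (length(v)) do.call(rbind, v) else {
    data.frame(file = character(), location = character(),
               message = character(), stringsAsFactors = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, input validation, trait estimation,
#' the animal-model fit, convergence diagnostics, posterior summaries and
#' (optionally) selection-response projection, writing every intermediate
#' table plus a machine-readable summary and a run log into
#' `config$output_dir`. A failed convergence diagnostic is reported in the
#' summary, not fatal.
#'
#' @param config a [run_config].
#' @return invisibly, a list with `traits`, `chain`, `diagnostics`,
#'   `summary` and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  logline <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = ""), "\n",
        file = logf, append = TRUE)
  }
  logline("run started; seed = ", config$seed)

  if (config$sim_mode) {
    logline("stage simulate: ", config$design$n_blocks, " blocks")
    design <- config$design
    design$seed <- config$seed
    dataset <- simulate_dataset(design, config$truth)
    data_dir <- file.path(out, "data")
    write_dataset(dataset, data_dir)
  } else {
    data_dir <- config$input_dir
  }

  logline("stage validate: ", data_dir)
  violations <- validate_tables(data_dir)
  if (nrow(violations)) {
    stop("input validation failed:\n",
         paste(sprintf("%s [%s]: %s", violations$file, violations$location,
                       violations$message), collapse = "\n"))
  }

  logline("stage traits")
  ped <- read_pedigree(file.path(data_dir, "pedigree.csv"))
  tanks <- read.csv(file.path(data_dir, "tanks.csv"),
                    stringsAsFactors = FALSE)
  counts <- read.csv(file.path(data_dir, "counts.csv"),
                     stringsAsFactors = FALSE)
  lengths <- read.csv(file.path(data_dir, "lengths.csv"),
                      stringsAsFactors = FALSE)
  traits <- build_trait_table(tanks, counts, lengths)
  write.csv(traits, file.path(out, "traits.csv"), row.names = FALSE)

  logline("stage fit: ", config$n_iter, " iterations")
  ms <- model_spec(traits, ped)
  prior <- prior_from_data(traits, nu = config$prior_nu)
  chain <- run_gibbs(ms, prior, n_iter = config$n_iter,
                     burn_in = config$burn_in, thin = config$thin,
                     seed = config$seed)
  write_chain(chain, file.path(out, "chain.csv"))

  logline("stage diagnose")
  diag <- tryCatch(convergence_diagnostics(chain), error = function(e) e)
  diag_ok <- is.data.frame(diag) && all(diag$passed)
  if (is.data.frame(diag)) {
    write.csv(diag, file.path(out, "diagnostics.csv"), row.names = FALSE)
  }

  logline("stage summarize")
  tn <- chain$trait_names
  h2 <- lapply(setNames(tn, tn), function(t) {
    s <- heritability(chain, t, interval = config$interval)
    s[c("mean", "lower", "upper")]
  })
  props <- variance_proportions(chain, interval = config$interval)
  pair <- function(f, x, y) {
    s <- f(chain, x, y, interval = config$interval)
    s[c("mean", "lower", "upper")]
  }
  summary <- list(
    seed = config$seed,
    n_samples = chain$n_samples,
    diagnostics_all_passed = diag_ok,
    heritability = h2,
    variance_proportions = props,
    r_G = list(
      mortality = pair(genetic_correlation, "mortality_ambient",
                       "mortality_acidified"),
      growth = pair(genetic_correlation, "growth_ambient",
                    "growth_acidified")),
    r_M = list(
      mortality = pair(maternal_correlation, "mortality_ambient",
                       "mortality_acidified"),
      growth = pair(maternal_correlation, "growth_ambient",
                    "growth_acidified")))

  if (!is.null(config$beta)) {
    logline("stage project")
    resp <- posterior_response(chain, config$beta,
                               interval = config$interval)
    write.csv(resp, file.path(out, "selection_response.csv"),
              row.names = FALSE)
    summary$selection_response <- resp
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_echo <- config[c("sim_mode", "n_iter", "burn_in", "thin", "seed",
                       "prior_nu", "interval")]
  jsonlite::write_json(cfg_echo, file.path(out, "config.json"),
                       auto_unbox = TRUE, force = TRUE)
  logline("run finished")
  invisible(list(traits = traits, chain = chain, diagnostics = diag,
                 summary = summary, output_dir = out))
}
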