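# Headless pipeline: simulate -> fit -> compare, driven by a flat key-value
# configuration file. Each stage writes plain-text tables that round-trip
# through the package's own readers.

.DEFAULT_CONFIG <- list(
  "cohorts.nh.n" = 14, "cohorts.ci.n" = 7,
  "design.n_auditory" = 40, "design.n_visual" = 40, "design.n_divided" = 100,
  "design.n_snr" = 8,
  "mcmc.chains" = 3, "mcmc.samples" = 10000, "mcmc.burn_in" = 10000,
  "mcmc.adapt" = 1000,
  "variant" = "trade-off", "constraint" = "aud_free_vis_shared",
  "truth_variant" = "trade-off", "seed" = 1)

#' Read a flat key-value run configuration
#'
#' Parses lines of the form \code{key = value} (dotted section names,
#' \code{#} comments), merged over the package defaults. Numeric-looking
#' values are converted to numbers.
#'
#' @param path configuration file path, or \code{NULL} for pure defaults.
#' @param overrides named list applied last (e.g. from command-line flags).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .DEFAULT_CONFIG
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  for (key in names(overrides))
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  bad <- vapply(cfg[grep("\\.n$|chains|samples|burn_in|adapt", names(cfg))],
                function(v) is.numeric(v) && v <= 0, logical(1))
  if (any(bad))
    stop("non-positive count(s) in config: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  cfg
}

.smoke_config <- function(cfg) {
  cfg[["mcmc.chains"]] <- 3
  cfg[["mcmc.samples"]] <- 2000
  cfg[["mcmc.burn_in"]] <- 1000
  cfg[["mcmc.adapt"]] <- 500
  cfg
}

.stage_log <- function(...) message(sprintf(...))

#' Simulate a synthetic study to disk
#'
#' Generates the two-cohort study defined by the configuration and writes
#' \code{trials.csv} (the Matrix-test trial table) and \code{truth.csv}
#' (the generating participant parameters, for recovery checks).
#'
#' @param config configuration list from [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(config = read_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(
    hypers = list(nh_hyperparams(), ci_hyperparams()),
    n = c(config[["cohorts.nh.n"]], config[["cohorts.ci.n"]]),
    truth_variant = config[["truth_variant"]],
    seed = as.integer(config[["seed"]]),
    n_auditory = config[["design.n_auditory"]],
    n_visual = config[["design.n_visual"]],
    n_divided = config[["design.n_divided"]],
    n_snr = config[["design.n_snr"]])
  trials_path <- file.path(out_dir, "trials.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_trials(sim$trials, trials_path)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  .stage_log("simulate: %d trials, %d participants, seed %d -> %s",
             nrow(sim$trials), nrow(sim$truth),
             as.integer(config[["seed"]]), trials_path)
  invisible(c(trials = trials_path, truth = truth_path))
}

#' Export posterior draws as a delimited table
#'
#' One row per retained draw with a \code{chain} column and one column per
#' monitored parameter.
#'
#' @param fit an \code{"av_fit"} object.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_posterior <- function(fit, path) {
  nchain <- ncol(fit$draws[[1]])
  tab <- data.frame(chain = rep(seq_len(nchain),
                                each = nrow(fit$draws[[1]])))
  for (nm in names(fit$draws)) tab[[nm]] <- as.numeric(fit$draws[[nm]])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Fit the hierarchical model per cohort and write the artifacts
#'
#' Runs [fit_av_model()] for each cohort in the trial table and writes, per
#' cohort, the posterior draws (\code{samples_<cohort>.csv}), the posterior
#' summary including the divided-minus-focused auditory lapse contrast
#' (\code{summary_<cohort>.csv}) and the convergence report
#' (\code{convergence_<cohort>.csv}).
#'
#' @param trials_path path to a trial CSV (schema of [write_trials()]).
#' @param config configuration list.
#' @param out_dir output directory.
#' @return List of \code{"av_fit"} objects, invisibly; attribute
#'   \code{"converged"} reports the overall convergence flag.
#' @export
cmd_fit <- function(trials_path, config = read_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_path)
  fits <- fit_cohorts(trials,
                      constraint = config[["constraint"]],
                      variant = config[["variant"]],
                      chains = as.integer(config[["mcmc.chains"]]),
                      samples = as.integer(config[["mcmc.samples"]]),
                      burn_in = as.integer(config[["mcmc.burn_in"]]),
                      adapt = as.integer(config[["mcmc.adapt"]]),
                      seed = as.integer(config[["seed"]]))
  converged <- TRUE
  for (cohort in names(fits)) {
    fit <- fits[[cohort]]
    write_posterior(fit, file.path(out_dir,
                                   sprintf("samples_%s.csv", cohort)))
    summ <- posterior_summary(fit)
    utils::write.csv(summ, file.path(out_dir,
                                     sprintf("summary_%s.csv", cohort)),
                     row.names = FALSE)
    diag <- diagnose(fit)
    utils::write.csv(diag, file.path(out_dir,
                                     sprintf("convergence_%s.csv", cohort)),
                     row.names = FALSE)
    converged <- converged && isTRUE(attr(diag, "pass"))
    .stage_log("fit %s: threshold %.2f dB, lapse diff %.3f, max Rhat %.3f",
               cohort, mean(fit$draws$group_threshold_a),
               mean(fit$draws$group_lapse_a_diff), max(diag$rhat, na.rm = TRUE))
  }
  structure(invisible(fits), converged = converged)
}

#' Compare model variants and write the report
#'
#' Writes the BIC comparison table (\code{comparison.csv}) and the
#' multisensory-enhancement-index grid per cohort (\code{mei_<cohort>.csv})
#' evaluated at the cohort-level posterior means.
#'
#' @param trials_path path to a trial CSV.
#' @param fits named list of \code{"av_fit"} objects per cohort (from
#'   [cmd_fit()]); used to initialize the ML refits and for the MEI grid.
#' @param config configuration list.
#' @param out_dir output directory.
#' @param snr_grid,blur_grid stimulus grids for the MEI surface.
#' @return The comparison data frame, invisibly.
#' @export
cmd_compare <- function(trials_path, fits, config = read_run_config(),
                        out_dir = ".",
                        snr_grid = seq(-20, 10, by = 2.5),
                        blur_grid = c(0, 6, 12, 16, 20)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_path)
  missing_fit <- setdiff(unique(trials$cohort), names(fits))
  if (length(missing_fit))
    stop("no fit supplied for cohort(s): ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  comp <- compare_variants(trials, init = fits,
                           constraint = config[["constraint"]])
  utils::write.csv(comp, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  for (cohort in names(fits)) {
    surf <- mei_surface(group_estimates(fits[[cohort]]), snr_grid, blur_grid)
    utils::write.csv(as.data.frame(surf),
                     file.path(out_dir, sprintf("mei_%s.csv", cohort)))
  }
  .stage_log("compare: wrote %s", file.path(out_dir, "comparison.csv"))
  invisible(comp)
}
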