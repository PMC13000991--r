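#' @title Run configuration and report assembly
#' @description Entry points tying the stages together: each `cmd_*`
#'   function resolves a run configuration, executes the corresponding
#'   analysis, writes its CSV outputs into the configured directory, and
#'   appends a plain-text log line recording the parameter-file digest, the
#'   seed, and the package version. A thin command-line wrapper around these
#'   functions ships in `inst/cli/fvcea.R`.
#' @name cli_report
NULL

.default_config <- function() {
  list(parameter_file = default_parameter_file(),
       outcome_modes = c("ever_cavity_avoided", "daly"),
       n_cycles = NULL,          # NULL = value from the parameter file
       discount_rate = NULL,
       psa_iterations = 1000,
       seed = 1,
       microsim_n = 100000,
       wtp_max = NULL,           # NULL = 2 x deterministic ICER
       wtp_steps = 200,
       output_dir = ".",
       accrual = "cycle_end")
}

#' Resolve a run configuration
#'
#' Reads an optional flat JSON configuration file and merges it under any
#' direct overrides; unspecified keys take package defaults (packaged
#' parameter table, both outcome modes, 1000 PSA iterations, seed 1).
#'
#' @param path Optional path to a JSON file with a flat key set.
#' @param overrides Named list applied on top of the file values (the CLI
#'   maps its flags here).
#' @return A validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  config <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    from_file <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(from_file), names(config))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    config[names(from_file)] <- from_file
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config[names(overrides)] <- overrides
  if (config$psa_iterations < 1) stop("psa_iterations must be >= 1")
  if (length(config$outcome_modes) == 0) stop("outcome_modes must be non-empty")
  config
}

# load parameters with config-level constant overrides applied
.config_params <- function(config) {
  ps <- load_parameter_table(config$parameter_file)
  if (!is.null(config$n_cycles)) {
    ps <- set_parameter(ps, "n_cycles", config$n_cycles)
    attr(ps, "free_horizon") <- TRUE
  }
  if (!is.null(config$discount_rate))
    ps <- set_parameter(ps, "discount_rate_annual", config$discount_rate)
  ps
}

.ensure_outdir <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir))
    stop("output directory is not writable: ", config$output_dir)
  config$output_dir
}

# reproducibility contract: every output is logged with the parameter-file
# digest, the seed in force, and the package version
.log_run <- function(config, what, files, seed = NA) {
  digest <- unname(tools::md5sum(config$parameter_file))
  line <- sprintf("%s | %s | params=%s md5=%s | seed=%s | fvcea %s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), what,
                  basename(config$parameter_file), digest,
                  ifelse(is.na(seed), "-", seed),
                  as.character(utils::packageVersion("fvcea")),
                  paste(basename(files), collapse = ","))
  cat(line, "\n", sep = "",
      file = file.path(config$output_dir, "run_log.txt"), append = TRUE)
  invisible(line)
}

#' Run the cost-effectiveness analysis and write its report files
#'
#' Writes per-arm trajectory CSVs and one strategy-comparison table per
#' configured outcome mode, plus a log entry.
#'
#' @param config A configuration list from [load_run_config()].
#' @return Named character vector of the written file paths, invisibly.
#' @export
cmd_run_cea <- function(config = load_run_config()) {
  ps <- .config_params(config)
  out <- .ensure_outdir(config)
  files <- character(0)
  for (arm in c("standard", "fv")) {
    traj <- propagate(build_transition_model(ps, arm),
                      ps$values[["n_cycles"]])
    f <- file.path(out, paste0("trajectory_", arm, ".csv"))
    write_trajectory(traj, f)
    files <- c(files, f)
  }
  for (mode in config$outcome_modes) {
    res <- run_cea(ps, mode, accrual = config$accrual)
    f <- file.path(out, paste0("cea_", mode, ".csv"))
    write_cea(res, f)
    files <- c(files, f)
  }
  .log_run(config, "run-cea", files)
  invisible(files)
}

#' Run the one-way deterministic sensitivity analysis
#'
#' Writes `tornado_<mode>.csv` (one row per varied parameter, sorted by
#' ICER range) per configured outcome mode.
#'
#' @param config A configuration list from [load_run_config()].
#' @return Written file paths, invisibly.
#' @export
cmd_run_dsa <- function(config = load_run_config()) {
  ps <- .config_params(config)
  out <- .ensure_outdir(config)
  files <- character(0)
  for (mode in config$outcome_modes) {
    f <- file.path(out, paste0("tornado_", mode, ".csv"))
    write_tornado(tornado(ps, mode, accrual = config$accrual), f)
    files <- c(files, f)
  }
  .log_run(config, "run-dsa", files)
  invisible(files)
}

#' Run the probabilistic sensitivity analysis
#'
#' Writes `psa_samples.csv` (incremental cost and effectiveness per
#' iteration for both outcomes) and one `ceac_<outcome>.csv` acceptability
#' curve per outcome.
#'
#' @param config A configuration list from [load_run_config()].
#' @return Written file paths, invisibly.
#' @export
cmd_run_psa <- function(config = load_run_config()) {
  ps <- .config_params(config)
  out <- .ensure_outdir(config)
  psa <- run_psa(ps, n_iter = config$psa_iterations, seed = config$seed,
                 accrual = config$accrual)
  f_samples <- file.path(out, "psa_samples.csv")
  write_psa_samples(psa, f_samples)
  files <- f_samples
  for (outcome in c("cavity", "daly")) {
    grid <- NULL
    if (!is.null(config$wtp_max))
      grid <- seq(0, config$wtp_max, length.out = config$wtp_steps + 1)
    f <- file.path(out, paste0("ceac_", outcome, ".csv"))
    write_ceac(ceac(psa, grid, outcome), f)
    files <- c(files, f)
  }
  .log_run(config, "run-psa", files, seed = config$seed)
  invisible(files)
}

#' Run the individual-level microsimulation
#'
#' Simulates both arms at the configured number of children and writes
#' `microsim_summary.csv` with end-state proportions (summing to one per
#' arm), mean discounted cost, and mean effectiveness per mode.
#'
#' @param config A configuration list from [load_run_config()].
#' @return Written file paths, invisibly.
#' @export
cmd_microsim <- function(config = load_run_config()) {
  ps <- .config_params(config)
  out <- .ensure_outdir(config)
  sched <- reward_schedule(ps, accrual = config$accrual)
  rows <- lapply(c("standard", "fv"), function(arm) {
    paths <- simulate_individuals(build_transition_model(ps, arm),
                                  n = config$microsim_n,
                                  n_cycles = ps$values[["n_cycles"]],
                                  seed = config$seed)
    s <- microsim_summary(paths, sched, ps)
    data.frame(arm = arm, n = s$n, t(s$proportions),
               mean_cost = s$mean_cost, se_cost = s$se_cost,
               t(s$effectiveness),
               ever_cavity_fraction = s$ever_cavity_fraction)
  })
  f <- file.path(out, "microsim_summary.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
  .log_run(config, "microsim", f, seed = config$seed)
  invisible(f)
}

#' Validate a parameter file
#'
#' Loads and validates the configured parameter file, printing the parameter
#' count on success; errors name the offending parameter and bound.
#'
#' @param config A configuration list from [load_run_config()].
#' @return The validated `fv_parameter_set`, invisibly.
#' @export
cmd_validate_params <- function(config = load_run_config()) {
  ps <- load_parameter_table(config$parameter_file)
  cat("parameter file OK:", config$parameter_file, "-",
      nrow(ps$table), "parameters\n")
  invisible(ps)
}
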