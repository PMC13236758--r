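# Configuration handling and result serialization.  Delimited outputs are
# comma-separated UTF-8 with a header row and '.' decimals; times are
# reported in both steps and seconds.

config_defaults <- function() {
  list(command = "simulate", preset = "conceptual_sor",
       isi_minutes = NULL, ri_minutes = NULL, habituation_minutes = NULL,
       task = "sor", delay_minutes = 2,
       n_points = 20000, n_runs = NULL, n_base = 1024, n_boot = 500,
       epsilons = c(0.05, 0.10, 0.15),
       seed = 1, out_dir = ".", data_file = NULL, verbose = FALSE,
       params = list())
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys, validates
#' parameter ranges, and fills canonical defaults for anything unset
#' (p1 0.75/0.25, pd1 0.1, pd2 0.02, L+ 0.25, L- 0.025, dt 3 s).
#'
#' @param path config file path.
#' @return List of class `sop_config` (the resolved configuration; element
#'   `params` is a full [sop_params()] object).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_sop_config(raw)
}

as_sop_config <- function(raw) {
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defs, raw)
  pkeys <- setdiff(names(raw$params), names(formals(sop_params)))
  if (length(pkeys))
    stop("unknown parameter keys: ", paste(pkeys, collapse = ", "))
  cfg$params <- do.call(sop_params, as.list(raw$params))
  if (!is.null(cfg$command) &&
      !cfg$command %in% c("simulate", "psp", "sobol", "local", "fit"))
    stop("unknown command '", cfg$command, "'")
  structure(cfg, class = "sop_config")
}

#' Save a configuration
#'
#' @param config an `sop_config` (or plain list of settings).
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_manifest <- function(out_dir, cfg, started) {
  manifest <- list(
    command = cfg$command, preset = cfg$preset, seed = cfg$seed,
    params = unclass(cfg$params),
    package_version = as.character(utils::packageVersion("soprec")),
    r_version = R.version.string,
    runtime_seconds = as.numeric(difftime(Sys.time(), started, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Execute a configured run
#'
#' Dispatches on `config$command` (`simulate`, `psp`, `sobol`, `local`,
#' `fit`), writes comma-separated result tables plus a JSON manifest
#' (parameters, seed, versions, runtime) into `config$out_dir`, and returns
#' the result object invisibly.  Outputs are deterministic given the seed.
#'
#' @param config an `sop_config` from [load_config()] (or a plain list of
#'   the same fields).
#' @return The computed result object, invisibly.
#' @export
run_command <- function(config) {
  if (!inherits(config, "sop_config")) config <- as_sop_config(config)
  started <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir)
  res <- switch(config$command,
    simulate = {
      preset <- resolve_preset(config)
      r <- run_preset(preset, config$params)
      write.csv(r$objects, file.path(out, "objects.csv"), row.names = FALSE)
      write.csv(r$contrasts, file.path(out, "contrasts.csv"),
                row.names = FALSE)
      r
    },
    psp = {
      r <- run_psp(n_points = config$n_points,
                   epsilons = config$epsilons,
                   n_runs = if (is.null(config$n_runs)) 5 else config$n_runs,
                   seed = config$seed, params = config$params)
      write.csv(r$proportions, file.path(out, "psp_proportions.csv"),
                row.names = FALSE)
      write.csv(r$regions, file.path(out, "psp_regions.csv"),
                row.names = FALSE)
      write.csv(r$constraints, file.path(out, "psp_constraints.csv"),
                row.names = FALSE)
      r
    },
    sobol = {
      r <- run_sobol(config$task, delay_minutes = config$delay_minutes,
                     n_base = config$n_base,
                     n_runs = if (is.null(config$n_runs)) 3 else config$n_runs,
                     n_boot = config$n_boot, seed = config$seed,
                     params = config$params)
      write.csv(r$indices, file.path(out, "sobol_indices.csv"),
                row.names = FALSE)
      write.csv(r$second_order, file.path(out, "sobol_second_order.csv"),
                row.names = FALSE)
      r
    },
    local = {
      r <- run_local_factorial(config$task,
                               delay_minutes = config$delay_minutes,
                               params = config$params)
      write.csv(r$effects, file.path(out, "factorial_effects.csv"),
                row.names = FALSE)
      r
    },
    fit = {
      if (is.null(config$data_file))
        stop("`fit` needs `data_file` (an empirical record table)")
      rec <- utils::read.csv(config$data_file, stringsAsFactors = FALSE)
      fit <- fit_k(rec)
      bt <- exact_study_bootstrap(rec)
      fit$ci95 <- bt$ci
      summary <- list(k = fit$k, ci95 = bt$ci,
                      n_records = nrow(rec),
                      n_resamples = bt$n_resamples,
                      loso = if (length(unique(rec$study)) >= 2) loso(rec))
      jsonlite::write_json(summary, file.path(out, "fit.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      fit
    })
  write_manifest(out, config, started)
  invisible(res)
}

resolve_preset <- function(cfg) {
  name <- cfg$preset
  extra <- list()
  for (nm in c("isi_minutes", "ri_minutes", "habituation_minutes"))
    if (!is.null(cfg[[nm]])) extra[[nm]] <- cfg[[nm]]
  if (startsWith(name, "conceptual_")) {
    do.call(conceptual_preset,
            c(list(task = sub("conceptual_", "", name)), extra))
  } else {
    do.call(empirical_preset, c(list(preset = name), extra))
  }
}

#' Write a synthetic empirical fixture table
#'
#' Emits a [generate_synthetic_studies()] table in the delimited
#' empirical-record format (columns `study`, `task`, `object`, `role`, `y`,
#' `se`, `a1_hat`), for observation-model tests and documentation.
#'
#' @param seed RNG seed.
#' @param path destination CSV path.
#' @param ... passed to [generate_synthetic_studies()].
#' @return The records, invisibly.
#' @export
write_fixture <- function(seed, path, ...) {
  rec <- generate_synthetic_studies(seed = seed, ...)
  write.csv(rec, path, row.names = FALSE)
  invisible(rec)
}
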