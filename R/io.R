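# File formats: codebook JSON, results CSV with a JSON parameter sidecar,
# and YAML run configurations.

#' Read / write a codebook as JSON
#'
#' The on-disk schema is
#' `{"symbols": [...], "noise_rate": x, "signal_rates": [[...], ...]}` with
#' full numeric precision; the reader validates all codebook invariants and
#' names the offending field on failure. A write/read round trip reproduces
#' the rates bit-exactly.
#'
#' @param codebook a `codebook`.
#' @param path file path.
#' @return `read_codebook` returns a `codebook`; `write_codebook` returns
#'   `path` invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "codebook"))
  obj <- list(symbols = codebook$symbols,
              noise_rate = codebook$noise_rate,
              signal_rates = unname(codebook$signal_rates))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    stop("malformed codebook JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (field in c("symbols", "noise_rate", "signal_rates")) {
    if (is.null(obj[[field]])) {
      stop("codebook JSON is missing required field `", field, "`",
           call. = FALSE)
    }
  }
  rates <- obj$signal_rates
  if (!is.matrix(rates)) rates <- as.matrix(rates)
  suppressWarnings(codebook(rates, obj$noise_rate, symbols = obj$symbols))
}

#' Write a results table with a parameter sidecar
#'
#' Writes a data.frame as a plain CSV (header row, '.' decimal, UTF-8, LF)
#' and a `<path>.json` sidecar embedding the full parameter set, seed and
#' package version needed to regenerate it. Identical parameters produce
#' byte-identical CSV bodies.
#'
#' @param results a data.frame.
#' @param path output CSV path.
#' @param params named list of run parameters (including the seed).
#' @param summary optional named list of summary quantities (fits, means)
#'   stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list(), summary = NULL) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    package = "ratechannel",
    version = as.character(utils::packageVersion("ratechannel")),
    params = params
  )
  if (!is.null(summary)) sidecar$summary <- summary
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# experiment name -> implementing function (shared by config reader and CLI)
.experiment_registry <- function() {
  list(
    "simulate" = run_batch,
    "hick" = hick_experiment,
    "hyman" = hyman_experiment,
    "prior-sweep" = prior_sweep_experiment,
    "practice" = practice_schedule,
    "sat" = sat_experiment,
    "stroop" = stroop_experiment,
    "learn-codebook" = learn_codebook,
    "sparsity" = sparsity_scaling_experiment
  )
}

#' Read / write a run configuration
#'
#' A run configuration is a YAML file with an `experiment` name (one of the
#' CLI subcommands) and a `params` mapping of arguments for that experiment.
#' Unknown experiments and unknown parameter keys are rejected; a written
#' configuration round-trips losslessly.
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a list with `experiment` and `params`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment)) {
    stop("config must name an `experiment`", call. = FALSE)
  }
  registry <- .experiment_registry()
  if (!cfg$experiment %in% names(registry)) {
    stop("unknown experiment `", cfg$experiment, "`; expected one of: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  params <- cfg$params
  if (is.null(params)) params <- list()
  extra <- setdiff(names(cfg), c("experiment", "params"))
  if (length(extra) > 0L) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  allowed <- .cli_param_names(cfg$experiment)
  unknown <- setdiff(names(params), allowed)
  if (length(unknown) > 0L) {
    stop("unknown parameters for `", cfg$experiment, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(experiment = cfg$experiment, params = params)
}

#' @rdname read_run_config
#' @param config a list with `experiment` and `params`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(config$experiment))
  yaml::write_yaml(list(experiment = config$experiment,
                        params = config$params), path)
  invisible(path)
}
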