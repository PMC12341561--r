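# Structured configuration, per-component seed derivation and run
# manifests: every command-line run resolves its config, derives its
# component seeds from one top-level seed, and writes exactly one JSON
# manifest recording inputs, outputs, seeds and per-stage counters.

#' Derive a per-component seed from a top-level seed
#'
#' Components (e.g. `"sampling"`, `"member3"`, `"bootstrap"`) get
#' reproducible, distinct seeds from one top-level seed by hashing the
#' component name into an offset: `(seed + 10007 * sum(utf8(name) * pos))
#' mod (2^31 - 1)`.
#'
#' @param seed top-level integer seed
#' @param component component name
#' @return integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, component) {
  codes <- utf8ToInt(component)
  h <- sum(codes * seq_along(codes)) %% 65537
  as.integer((as.numeric(seed) + 10007 * h) %% (2^31 - 1) + 1)
}

#' Load a structured configuration file
#'
#' YAML key-value hierarchy; missing files or keys outside the schema of
#' the requested subcommand raise a usage error naming the offending
#' keys.
#'
#' @param path YAML file path
#' @param schema optional character vector of allowed top-level keys
#' @return named list.
#' @export
load_config <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(schema)) {
    bad <- setdiff(names(cfg), schema)
    if (length(bad) > 0L)
      stop("config keys outside the schema: ", paste(bad, collapse = ", "),
           " (allowed: ", paste(schema, collapse = ", "), ")")
  }
  cfg
}

#' Write a run manifest
#'
#' Records the subcommand, the fully resolved configuration, seeds,
#' input/output paths, package version, wall time and per-stage
#' counters (frames read, trajectories propagated, force evaluations)
#' as JSON.  Exactly one manifest is written per run, also on failure.
#'
#' @param path output JSON path
#' @param subcommand the executed subcommand
#' @param config resolved configuration list
#' @param seeds named list of seeds used
#' @param inputs,outputs character vectors of paths
#' @param counters named list of per-stage counters
#' @param status "ok" or an error message
#' @param wall_time elapsed seconds
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, config = list(), seeds = list(),
                           inputs = character(0), outputs = character(0),
                           counters = list(), status = "ok", wall_time = NA) {
  manifest <- list(
    subcommand = subcommand,
    version = as.character(utils::packageVersion("deltadyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status,
    wall_time_s = wall_time,
    config = config,
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    counters = counters)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest JSON path
#' @return named list.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
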