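## Structured configuration files (YAML): interaction constants and
## simulation settings in one place, echoed back on load so every run
## documents the parameters in effect.

#' Read a configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration with optional
#' sections `interaction` (arguments of [interaction_params]) and
#' `simulation` (arguments of [sim_config]), applies defaults for missing
#' keys and echoes all parameters in effect.
#'
#' @param path path to the YAML/JSON file.
#' @param quiet suppress the parameter echo.
#' @return A list with elements `interaction` (an [interaction_params] if
#'   the section is present), `simulation` (list of [sim_config] arguments)
#'   and `raw` (the parsed file).
#' @export
read_config <- function(path, quiet = FALSE) {
  # YAML 1.1 would read the bare key `N` (mesh size) as a boolean; keep the
  # single-letter forms as strings and only word forms as logicals
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x))
  out <- list(raw = raw)
  if (!is.null(raw$interaction)) {
    known <- c("A", "lam", "H", "A_st", "lam_st", "a_cut", "steric")
    bad <- setdiff(names(raw$interaction), known)
    if (length(bad)) stop("unknown interaction key(s): ",
                          paste(bad, collapse = ", "))
    out$interaction <- do.call(interaction_params, raw$interaction)
  }
  if (!is.null(raw$simulation)) {
    known <- names(formals(sim_config))
    bad <- setdiff(names(raw$simulation), known)
    if (length(bad)) stop("unknown simulation key(s): ",
                          paste(bad, collapse = ", "))
    out$simulation <- raw$simulation
  }
  if (!quiet) {
    if (!is.null(out$interaction)) print(out$interaction)
    if (!is.null(out$simulation)) {
      cat("Simulation settings:\n")
      for (k in names(out$simulation)) {
        cat(sprintf("  %s = %s\n", k, format(out$simulation[[k]])))
      }
    }
  }
  out
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seeds, package version and
#' timestamp next to an output file so results can be regenerated.
#'
#' @param path manifest path (JSON).
#' @param command character label of the stage.
#' @param config list of parameters in effect.
#' @param seed the seed(s) used.
#' @param outputs character vector of produced files.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs = character()) {
  man <- list(command = command,
              config = config,
              seed = seed,
              package_version = as.character(utils::packageVersion("lamstack")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}
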