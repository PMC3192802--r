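#' Read a structured configuration file (YAML or JSON)
#'
#' Configuration files have optional sections `geometry`, `calibration`,
#' `solver`, `scene` and `calcium`; every value overrides the package
#' default of the corresponding function argument. Times given in ms
#' (keys ending in `_ms`) are converted by the consuming functions.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Build a compartment specification from a configuration list
#'
#' Uses `config$geometry` (fields `L`, `eps`, `a`, `D`) when present;
#' otherwise calibrates from `config$calibration` (fields
#' `target_ratio`, `a`, `calibration_ratio`, `D`).
#'
#' @param config A list from [read_config()].
#' @return A [compartment_spec()].
#' @export
spec_from_config <- function(config) {
  g <- config$geometry
  if (!is.null(g$L) && !is.null(g$eps)) {
    return(compartment_spec(L = g$L, eps = g$eps, a = g$a %||% 0.5,
                            D = g$D %||% 400))
  }
  cal <- config$calibration %||% list()
  calibrate_geometry(target_ratio = cal$target_ratio %||% 0.05,
                     a = g$a %||% cal$a %||% 0.5,
                     calibration_ratio = cal$calibration_ratio %||% 0.1,
                     D = g$D %||% cal$D %||% 400)
}

#' Write a reproducibility manifest next to a CLI output
#'
#' Records the resolved configuration, seed, package version and call so
#' an output directory can be regenerated bit-identically.
#'
#' @param dir Output directory.
#' @param command Subcommand name.
#' @param config Resolved configuration list.
#' @param seed Seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command, seed = seed,
    package = "dendrocrowd",
    version = as.character(utils::packageVersion("dendrocrowd")),
    config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
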