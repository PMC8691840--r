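#' Read a run configuration (YAML or JSON)
#'
#' Configuration files drive the command-line entry points; the format is
#' chosen by extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
}

#' Echo the effective configuration into an output directory
#'
#' @param config Named list.
#' @param dir Output directory (created if missing).
#' @param name File name.
#' @return The path written, invisibly.
#' @export
write_config_echo <- function(config, dir, name = "config_used.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, name)
  jsonlite::write_json(config, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(p)
}
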