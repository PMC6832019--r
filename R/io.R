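#' Read and write model parameter files
#'
#' Parameter sets are stored as flat key-value mappings (YAML or JSON,
#' chosen by file extension) with exactly the twelve keys
#' `lambda1 ... deltaP, phi`.  Unknown or missing keys are rejected by name.
#'
#' @param path file to read or write (`.yaml`/`.yml` or `.json`).
#' @return `read_params()` returns a validated [model_params()];
#'   `write_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(model_params(), f)
#' read_params(f)
#' @export
read_params <- function(path) {
  raw <- read_keyvalue(path)
  if (!is.null(raw$params) && is.list(raw$params)) raw <- raw$params
  unknown <- setdiff(names(raw), .param_names)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.param_names, names(raw))
  if (length(missing))
    stop("missing parameter key(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(model_params, raw[.param_names])
}

#' @rdname read_params
#' @param params a [model_params()] object.
#' @export
write_params <- function(params, path) {
  write_keyvalue(lapply(unclass(params), identity), path)
  invisible(path)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

write_keyvalue <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(x, path, precision = 15)
}

#' Write a table as TSV
#'
#' Tab-separated output with a header row, floating-point values at 12
#' significant digits, and rows in the order given - so re-running a seeded
#' computation writes a byte-identical file.
#'
#' @param df a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.12g", out[[j]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write table to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

.config_keys <- c("params", "analyze", "simulate", "gillespie", "sweep",
                  "pulse", "outdir", "seed", "log_level")

#' Load and save run configurations
#'
#' A run configuration is a YAML/JSON document with a mandatory `params`
#' block (validated through [model_params()]) and optional per-subcommand
#' blocks (`analyze`, `simulate`, `gillespie`, `sweep`, `pulse`) plus
#' `outdir`, `seed` and `log_level`.  Unknown top-level keys are rejected by
#' name, and a configuration round-trips losslessly through
#' `save_config()`/`load_config()`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return `load_config()` returns a validated list of class `run_config`;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- read_keyvalue(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(raw$params))
    stop("config ", path, " lacks the mandatory 'params' block",
         call. = FALSE)
  raw$params <- do.call(model_params, raw$params)
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  structure(raw, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config` (or compatible list).
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$params <- lapply(unclass(x$params), identity)
  write_keyvalue(x, path)
  invisible(path)
}
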