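#' Read a minimal YAML-subset configuration file
#'
#' Parses the flat key/value configuration dialect used for scheme and run
#' configuration files. Supported syntax: `key: value` lines, double- or
#' single-quoted strings, inline lists `[a, b, c]`, comment lines starting
#' with `#`, and blank lines. Nested mappings are not supported; anything
#' richer (e.g. a category lookup table) is referenced as a companion CSV
#' file. Scalars that look numeric are returned as numerics.
#'
#' @param path path to the configuration file.
#' @return named list of scalars and character/numeric vectors.
#' @export
read_simple_yaml <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3) {
      stop("cannot parse configuration line: ", sQuote(ln), call. = FALSE)
    }
    out[[m[2]]] <- parse_yaml_scalar(m[3])
  }
  out
}

parse_yaml_scalar <- local({
  scalar1 <- function(v) {
    # quoted scalars are always strings (protects e.g. "0123456789")
    if (grepl('^".*"$', v)) return(sub('^"(.*)"$', "\\1", v))
    if (grepl("^'.*'$", v)) return(sub("^'(.*)'$", "\\1", v))
    if (grepl("^-?[0-9]+$", v)) return(as.integer(v))
    if (grepl("^-?[0-9]*\\.[0-9]+([eE][+-]?[0-9]+)?$", v)) return(as.numeric(v))
    if (identical(v, "true")) return(TRUE)
    if (identical(v, "false")) return(FALSE)
    v
  }
  function(v) {
    if (grepl("^\\[.*\\]$", v)) {
      inner <- substr(v, 2, nchar(v) - 1L)
      if (!nzchar(trimws(inner))) return(character(0))
      parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
      vals <- lapply(parts, scalar1)
      if (all(vapply(vals, is.numeric, logical(1)))) return(unlist(vals))
      return(vapply(vals, as.character, character(1)))
    }
    scalar1(v)
  }
})

#' Fingerprint an R configuration object
#'
#' Stable 64-bit FNV-1a hash of the canonical JSON rendering of a
#' configuration list; used to stamp artifacts so downstream stages can
#' verify they were produced under the same configuration.
#'
#' @param x a list of configuration values (must be JSON-representable).
#' @return a 16-character lowercase hex string.
#' @export
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  .fnv1a64(as.character(js))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# data/configuration errors carry a class so the CLI can exit 2 for user
# errors and 3 for internal contract failures
stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("occ_data_error", "error", "condition")))
}
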