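#' Define a hierarchical occupational classification scheme
#'
#' A scheme describes how a classification's code strings are structured:
#' how many significant characters a full code has, which prefixes define
#' the coarser coding levels, which separator characters appear in the
#' canonical rendering (e.g. `1-21.10`), which character marks positions an
#' expert could not code, and which characters are legal at each position.
#'
#' Each element of `levels` is either a prefix length (an integer: the
#' level's category is the significant prefix of that length) or a named
#' character vector (a lookup level: names are fixed-width significant
#' prefixes, values the coarser category labels, as in activity-sector
#' nomenclatures whose top-level sections group 2-digit divisions).
#'
#' @param name scheme name.
#' @param levels ordered list of level definitions, coarsest first; prefix
#'   lengths must be strictly increasing and the deepest level equals the
#'   full code length.
#' @param separators optional character vector of `"pos:char"` entries: in
#'   the canonical rendering, `char` is inserted after significant position
#'   `pos` (e.g. `c("1:-", "3:.")`).
#' @param placeholder single character marking uncodable positions.
#' @param alphabet `NULL` (any ASCII letter or digit), a single string of
#'   allowed characters applying to every position, or a character vector
#'   with one string per code position.
#' @return an object of class `scheme_spec`.
#' @seealso [parse_code()], [truncate_code()], [read_scheme()]
#' @export
#' @examples
#' isco88 <- scheme_spec("ISCO-88-like", levels = list(1, 2, 3, 4),
#'                       alphabet = "0123456789")
#' parse_code(isco88, "2221")
scheme_spec <- function(name, levels, separators = character(0),
                        placeholder = "#", alphabet = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(levels) || length(levels) == 0L) {
    stop_data("`levels` must be a non-empty list")
  }
  if (nchar(placeholder) != 1L) stop_data("`placeholder` must be one character")

  depth <- vapply(levels, function(l) {
    if (is.numeric(l) && length(l) == 1L) return(as.integer(l))
    if (is.character(l) && !is.null(names(l))) {
      w <- unique(nchar(names(l)))
      if (length(w) != 1L) stop_data("lookup level keys must share one width")
      return(as.integer(w))
    }
    stop_data("each level must be a prefix length or a named lookup vector")
  }, integer(1))
  is_lookup <- vapply(levels, is.character, logical(1))

  plen <- depth[!is_lookup]
  if (any(diff(plen) <= 0)) {
    stop_data("prefix lengths must strictly increase across levels")
  }
  if (any(diff(depth) < 0)) {
    stop_data("level depths must be non-decreasing")
  }
  full <- depth[length(depth)]
  if (is_lookup[length(is_lookup)]) {
    stop_data("the deepest level must be a prefix level spanning the full code")
  }
  for (l in levels[is_lookup]) {
    if (any(grepl(placeholder, names(l), fixed = TRUE))) {
      stop_data("placeholder may not appear in a lookup table key")
    }
  }

  sep <- parse_separators(separators, full)

  if (!is.null(alphabet)) {
    if (length(alphabet) == 1L) alphabet <- rep(alphabet, full)
    if (length(alphabet) != full) {
      stop_data("`alphabet` must have one entry per code position")
    }
  }

  structure(list(name = name, levels = levels, depth = depth,
                 is_lookup = is_lookup, full_length = full,
                 separators = sep, placeholder = placeholder,
                 alphabet = alphabet),
            class = "scheme_spec")
}

parse_separators <- function(separators, full) {
  if (length(separators) == 0L) {
    return(data.frame(pos = integer(0), char = character(0)))
  }
  parts <- strsplit(separators, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop_data("separators must be of the form \"pos:char\"")
  pos <- as.integer(vapply(parts, `[`, character(1), 1L))
  char <- vapply(parts, `[`, character(1), 2L)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos >= full)) {
    stop_data("separator positions must lie strictly inside the code")
  }
  if (any(nchar(char) != 1L)) stop_data("separator must be one character")
  data.frame(pos = pos, char = char)[order(pos), , drop = FALSE]
}

#' @export
print.scheme_spec <- function(x, ...) {
  kind <- ifelse(x$is_lookup, paste0("lookup(", x$depth, ")"), x$depth)
  cat(sprintf("<scheme_spec> %s: %d levels [%s], code length %d, placeholder %s\n",
              x$name, length(x$levels), paste(kind, collapse = ", "),
              x$full_length, sQuote(x$placeholder)))
  invisible(x)
}

#' Number of coding levels of a scheme
#' @param scheme a [scheme_spec()].
#' @return integer count of levels.
#' @export
n_levels <- function(scheme) {
  stopifnot(inherits(scheme, "scheme_spec"))
  length(scheme$levels)
}

#' Read a scheme definition file
#'
#' Scheme files use the configuration dialect of [read_simple_yaml()] with
#' keys `name`, `placeholder`, `levels` (integers, or the string
#' `"lookup:<width>"` for a lookup level), `separators`, `alphabet` and,
#' when a lookup level is present, `lookup_file`: a two-column CSV
#' (`prefix,label`) resolved relative to the scheme file.
#'
#' @param path path to the scheme configuration file.
#' @return a [scheme_spec()].
#' @export
read_scheme <- function(path) {
  cfg <- read_simple_yaml(path)
  for (k in c("name", "levels")) {
    if (is.null(cfg[[k]])) stop_data("scheme file misses key ", sQuote(k))
  }
  lv <- as.list(cfg$levels)
  lookup_tab <- NULL
  if (!is.null(cfg$lookup_file)) {
    lf <- file.path(dirname(path), cfg$lookup_file)
    tab <- read.csv(lf, colClasses = "character")
    lookup_tab <- setNames(tab$label, tab$prefix)
  }
  lv <- lapply(lv, function(l) {
    if (is.character(l) && grepl("^lookup:", l)) {
      if (is.null(lookup_tab)) stop_data("lookup level requires `lookup_file`")
      w <- as.integer(sub("^lookup:", "", l))
      if (any(nchar(names(lookup_tab)) != w)) {
        stop_data("lookup_file prefixes do not match declared width ", w)
      }
      return(lookup_tab)
    }
    if (is.character(l)) return(as.integer(l))
    l
  })
  alphabet <- cfg$alphabet
  if (!is.null(alphabet)) alphabet <- as.character(alphabet)
  scheme_spec(name = cfg$name, levels = lv,
              separators = as.character(cfg$separators %||% character(0)),
              placeholder = cfg$placeholder %||% "#",
              alphabet = alphabet)
}

#' Built-in approximate scheme definitions
#'
#' Ships structural approximations of four classifications used in
#' occupational epidemiology: `"naf2008"` (5 levels; level 1 is a section
#' lookup over the 2-digit division), `"pcs2003"` (4 levels, 3 digits + a
#' letter), `"isco88"` (4 digit levels) and `"isco68"` (4 levels,
#' `1-21.10`-style rendering). These encode level structure only, not the
#' official nomenclature titles.
#'
#' @param name one of `"naf2008"`, `"pcs2003"`, `"isco88"`, `"isco68"`.
#' @return a [scheme_spec()].
#' @export
builtin_scheme <- function(name = c("naf2008", "pcs2003", "isco88", "isco68")) {
  name <- match.arg(name)
  path <- system.file("extdata", "schemes", paste0(name, ".yaml"),
                      package = "occucode", mustWork = TRUE)
  read_scheme(path)
}

#' Write a scheme definition file
#'
#' Serializes a prefix-level scheme into the configuration dialect read by
#' [read_scheme()]. Lookup levels are written to a companion
#' `<name>_lookup.csv` next to the file.
#'
#' @param scheme a [scheme_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "scheme_spec"))
  lv <- character(length(scheme$levels))
  lookup_file <- NULL
  for (i in seq_along(scheme$levels)) {
    if (scheme$is_lookup[i]) {
      if (!is.null(lookup_file)) {
        stop_data("only one lookup level can be serialized")
      }
      lookup_file <- paste0(sub("\\.[^.]*$", "", basename(path)),
                            "_lookup.csv")
      tab <- scheme$levels[[i]]
      write.csv(data.frame(prefix = names(tab), label = unname(tab)),
                file.path(dirname(path), lookup_file), row.names = FALSE)
      lv[i] <- paste0("lookup:", scheme$depth[i])
    } else {
      lv[i] <- as.character(scheme$depth[i])
    }
  }
  lines <- c(
    paste0("name: ", scheme$name),
    paste0("placeholder: \"", scheme$placeholder, "\""),
    paste0("levels: [", paste(lv, collapse = ", "), "]"),
    paste0("separators: [",
           if (nrow(scheme$separators)) {
             paste0("\"", scheme$separators$pos, ":", scheme$separators$char,
                    "\"", collapse = ", ")
           } else "",
           "]"))
  if (!is.null(lookup_file)) {
    lines <- c(lines, paste0("lookup_file: ", lookup_file))
  }
  if (!is.null(scheme$alphabet)) {
    lines <- c(lines, paste0("alphabet: [",
                             paste0("\"", scheme$alphabet, "\"",
                                    collapse = ", "), "]"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Parse raw code strings against a scheme
#'
#' Strips whitespace and separator characters, upper-cases, validates every
#' character against the scheme's alphabet (the placeholder is always
#' allowed) and right-pads codes shorter than the full length with
#' placeholders — the convention of classifications that record only the
#' codable levels (e.g. `1-21` standing for `1-21.##`).
#'
#' @param scheme a [scheme_spec()].
#' @param raw character vector of code strings.
#' @return an `occ_codes` object (vector-like; see [code_canonical()],
#'   [is_complete()], [truncate_code()]).
#' @export
#' @examples
#' sc <- builtin_scheme("isco68")
#' code_canonical(parse_code(sc, c("1-21.10", "1-21")))
parse_code <- function(scheme, raw) {
  stopifnot(inherits(scheme, "scheme_spec"))
  raw <- as.character(raw)
  stripped <- gsub("\\s+", "", raw)
  if (any(!nzchar(stripped))) {
    stop_data("empty code string at index ",
              which(!nzchar(stripped))[1])
  }
  for (ch in unique(scheme$separators$char)) {
    stripped <- gsub(ch, "", stripped, fixed = TRUE)
  }
  stripped <- toupper(stripped)
  len <- nchar(stripped)
  if (any(len > scheme$full_length)) {
    i <- which(len > scheme$full_length)[1]
    stop_data("invalid code ", sQuote(raw[i]), ": longer than the scheme's ",
              scheme$full_length, " significant characters")
  }
  pad <- strrep(scheme$placeholder, scheme$full_length - len)
  sig <- paste0(stripped, pad)

  chars <- matrix(unlist(strsplit(sig, "", fixed = TRUE)),
                  nrow = length(sig), byrow = TRUE)
  for (p in seq_len(scheme$full_length)) {
    allowed <- if (is.null(scheme$alphabet)) {
      NULL
    } else {
      strsplit(scheme$alphabet[p], "", fixed = TRUE)[[1]]
    }
    cp <- chars[, p]
    ok <- cp == scheme$placeholder |
      (if (is.null(allowed)) grepl("^[0-9A-Z]$", cp) else cp %in% allowed)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop_data("invalid code ", sQuote(raw[i]), ": character ",
                sQuote(cp[i]), " not allowed at position ", p)
    }
  }
  new_occ_codes(scheme, sig)
}

new_occ_codes <- function(scheme, significant) {
  structure(list(scheme = scheme, significant = significant),
            class = "occ_codes")
}

#' @export
length.occ_codes <- function(x) length(x$significant)

#' @export
`[.occ_codes` <- function(x, i) new_occ_codes(x$scheme, x$significant[i])

#' @export
print.occ_codes <- function(x, ...) {
  cat(sprintf("<occ_codes> %d code(s) in scheme %s\n", length(x),
              x$scheme$name))
  print(code_canonical(x))
  invisible(x)
}

#' @export
format.occ_codes <- function(x, ...) code_canonical(x)

#' Canonical rendering of parsed codes
#'
#' Renders significant characters with the scheme's separators reinserted
#' up to the last non-placeholder position; trailing placeholders are
#' dropped (so a partially coded entry prints as e.g. `1-21`, not
#' `1-21.##`). An all-placeholder code renders as the bare placeholder run.
#'
#' @param codes an `occ_codes` object from [parse_code()].
#' @return character vector of canonical code strings.
#' @export
code_canonical <- function(codes) {
  stopifnot(inherits(codes, "occ_codes"))
  sc <- codes$scheme
  ph <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", sc$placeholder)
  vapply(codes$significant, function(sig) {
    trimmed <- sub(paste0("(", ph, ")+$"), "", sig)
    if (!nzchar(trimmed)) return(sig)
    render_prefix(sc, trimmed)
  }, character(1), USE.NAMES = FALSE)
}

render_prefix <- function(scheme, prefix) {
  sep <- scheme$separators
  out <- prefix
  if (nrow(sep)) {
    for (i in rev(seq_len(nrow(sep)))) {
      if (nchar(prefix) > sep$pos[i]) {
        out <- paste0(substr(out, 1, sep$pos[i]), sep$char[i],
                      substr(out, sep$pos[i] + 1L, nchar(out)))
      }
    }
  }
  out
}

#' Is a code complete (free of placeholders)?
#'
#' Entries whose gold-standard code is incomplete are not viable for
#' classifier training, since the system must suggest complete codes.
#'
#' @param codes an `occ_codes` object.
#' @return logical vector.
#' @export
is_complete <- function(codes) {
  stopifnot(inherits(codes, "occ_codes"))
  !grepl(codes$scheme$placeholder, codes$significant, fixed = TRUE)
}

#' Truncate codes to a coding level
#'
#' Returns each code's category label at the requested level: the rendered
#' significant prefix for prefix levels, or the mapped coarse category for
#' lookup levels (an unmapped key falls back to the raw prefix). A
#' placeholder inside the requested prefix raises a not-codable error.
#'
#' @param codes an `occ_codes` object.
#' @param level coding level, `1` (coarsest) to [n_levels()].
#' @return character vector of level labels.
#' @export
#' @examples
#' sc <- builtin_scheme("isco88")
#' truncate_code(parse_code(sc, "2221"), 2)  # "22"
truncate_code <- function(codes, level) {
  stopifnot(inherits(codes, "occ_codes"))
  sc <- codes$scheme
  if (length(level) != 1L || level < 1L || level > length(sc$levels)) {
    stop_data("`level` must be in 1..", length(sc$levels))
  }
  w <- sc$depth[level]
  prefix <- substr(codes$significant, 1L, w)
  bad <- grepl(sc$placeholder, prefix, fixed = TRUE)
  if (any(bad)) {
    stop_data("code ", sQuote(code_canonical(codes[which(bad)[1]])),
              " is not codable at level ", level,
              ": placeholder inside the level prefix")
  }
  if (sc$is_lookup[level]) {
    tab <- sc$levels[[level]]
    lab <- unname(tab[prefix])
    lab[is.na(lab)] <- prefix[is.na(lab)]
    return(lab)
  }
  vapply(prefix, render_prefix, character(1), scheme = sc, USE.NAMES = FALSE)
}

#' Count distinct outcome categories at a coding level
#'
#' The number of distinct categories ("outcome categories") into which a
#' collection of codes falls at a level; non-decreasing in level by the
#' nesting of the hierarchy.
#'
#' @param codes an `occ_codes` object.
#' @param level coding level.
#' @return non-negative integer.
#' @export
count_outcome_categories <- function(codes, level) {
  if (length(codes) == 0L) return(0L)
  length(unique(truncate_code(codes, level)))
}
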