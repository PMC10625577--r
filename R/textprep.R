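#' Normalize a free-text job description into tokens
#'
#' Applies the standard short-text normalization pipeline: NFC Unicode
#' normalization, lower-casing, replacement of punctuation by spaces,
#' whitespace tokenization, and stemming. Supported language tags: `"en"`
#' (English Snowball stemming) and `"none"` (no stemming; used for
#' synthetic corpora whose abstract tokens are stemming-invariant, and for
#' embedders that expect raw surface forms).
#'
#' @param text character vector of free texts (empty or `NA` gives an
#'   empty token sequence).
#' @param language language tag; see Details.
#' @return for a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
#' @examples
#' normalize_text("Service Employee.")  # "servic" "employe"
normalize_text <- function(text, language = "en") {
  supported <- c("en", "none")
  if (!language %in% supported) {
    stop_data("unsupported language tag ", sQuote(language),
              "; supported: ", paste(supported, collapse = ", "))
  }
  out <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    x <- enc2utf8(as.character(x))
    # NFC so that composed/decomposed accents normalize identically
    x <- iconv(x, from = "UTF-8", to = "UTF-8")
    x <- tolower(x)
    x <- gsub("[[:punct:]]+", " ", x)
    toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (language == "en") toks <- stem_tokens(toks)
    toks
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Deterministic hashed bag-of-stems sentence embedder
#'
#' The default embedder: each normalized token is hashed (FNV-1a) into one
#' of `dim` buckets with a pseudo-random sign, and a text's vector is the
#' signed bucket count of its tokens. It is fully deterministic, requires
#' no model download, maps empty text to the zero vector, and gives texts
#' with disjoint vocabularies orthogonal vectors in expectation.
#'
#' @param dim embedding dimension (default 256).
#' @param language language tag passed to [normalize_text()].
#' @return an object of class `occ_embedder`.
#' @seealso [custom_embedder()] for plugging in a pretrained
#'   sentence-embedding model.
#' @export
hash_embedder <- function(dim = 256L, language = "en") {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  new_embedder(
    embed = function(texts) {
      toks <- normalize_text(texts, language = language)
      if (length(texts) == 1L) toks <- list(toks)
      .hash_embed(toks, dim)
    },
    dim = dim,
    identifier = sprintf("hash-bos-%d-%s-v1", dim, language),
    spec = list(type = "hash", dim = dim, language = language)
  )
}

#' Wrap an external sentence-embedding model
#'
#' Adapter for pretrained sentence embedders. `fn` receives a character
#' vector of raw texts (no stemming is applied: pretrained sentence models
#' expect surface forms) and must return a numeric matrix with one row per
#' text and `dim` columns, deterministically. Models wrapped this way
#' cannot be serialized into a coder bundle; reloading a coder trained
#' with one requires re-supplying the embedder.
#'
#' @param fn embedding function, `character -> matrix`.
#' @param dim embedding dimension `fn` returns.
#' @param identifier stable identifier recorded in artifacts.
#' @return an object of class `occ_embedder`.
#' @export
custom_embedder <- function(fn, dim, identifier) {
  stopifnot(is.function(fn), dim >= 1)
  new_embedder(embed = fn, dim = as.integer(dim), identifier = identifier,
               spec = list(type = "custom", dim = as.integer(dim)))
}

new_embedder <- function(embed, dim, identifier, spec) {
  structure(list(embed = embed, dim = dim, identifier = identifier,
                 spec = spec),
            class = "occ_embedder")
}

#' @export
print.occ_embedder <- function(x, ...) {
  cat(sprintf("<occ_embedder> %s (dim %d)\n", x$identifier, x$dim))
  invisible(x)
}

embedder_from_spec <- function(spec) {
  if (identical(spec$type, "hash")) {
    return(hash_embedder(dim = spec$dim, language = spec$language))
  }
  stop_data("embedder of type ", sQuote(spec$type %||% "?"),
            " cannot be reconstructed; pass `embedder=` explicitly")
}

embed_texts <- function(embedder, texts) {
  stopifnot(inherits(embedder, "occ_embedder"))
  m <- embedder$embed(as.character(texts))
  if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != embedder$dim) {
    stop("internal contract violation: embedder ", embedder$identifier,
         " returned wrong shape", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("internal contract violation: non-finite embedding values",
         call. = FALSE)
  }
  m
}

#' Embed job-episode records by summing per-class embeddings
#'
#' Each requested input class (e.g. occupation and sector free texts) is
#' embedded separately and the vectors are summed elementwise, so the
#' fused representation is order-independent and a missing or empty class
#' is a no-op.
#'
#' @param records data frame of job episodes, one text column per input
#'   class (a requested class absent from the data is treated as empty
#'   text).
#' @param embedder an [hash_embedder()] or [custom_embedder()].
#' @param input_classes character vector of input-class column names.
#' @return list with `matrix` (one row per record) and `entry_id`.
#' @export
build_feature_matrix <- function(records, embedder, input_classes) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            length(input_classes) >= 1L)
  acc <- matrix(0, nrow = nrow(records), ncol = embedder$dim)
  for (cls in input_classes) {
    texts <- if (cls %in% names(records)) {
      ifelse(is.na(records[[cls]]), "", as.character(records[[cls]]))
    } else {
      rep("", nrow(records))
    }
    acc <- acc + embed_texts(embedder, texts)
  }
  list(matrix = acc,
       entry_id = as.character(records$entry_id %||% seq_len(nrow(records))))
}

#' Read a job-episode table from CSV
#'
#' Expects UTF-8 CSV with an `entry_id` column, free-text input-class
#' columns, and optionally a gold-standard code column named `gold`.
#' Column names can be remapped via `columns`.
#'
#' @param path CSV path.
#' @param columns optional named character vector mapping file column
#'   names to canonical names, e.g. `c(profession = "occupation")` renames
#'   the file's `profession` column to `occupation`.
#' @param sep field delimiter, default comma.
#' @return data frame of records with character columns.
#' @export
read_episodes <- function(path, columns = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, colClasses = "character",
                 fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(columns)) {
    for (i in seq_along(columns)) {
      from <- names(columns)[i]
      if (from %in% names(df)) names(df)[names(df) == from] <- columns[[i]]
    }
  }
  if (!"entry_id" %in% names(df)) {
    stop_data("episodes file misses an `entry_id` column: ", path)
  }
  if (anyDuplicated(df$entry_id)) {
    stop_data("duplicate entry_id values in ", path)
  }
  df
}
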