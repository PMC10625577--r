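# Synthetic schemes, corpora, coding indexes and JEMs with the structural
# signature of real occupational cohorts: very short descriptions (median
# 1-3 words), power-law class imbalance down to singleton classes,
# placeholder-incomplete gold codes, and matrices in which only a small
# fraction of codes carries non-zero exposure.  Tokens are abstract
# alphanumerics chosen so that stemming is the identity on them.

SYNTH_ALPHABET <- c(0:9, LETTERS)

#' Generate a prefix-structured classification scheme
#'
#' Builds a scheme whose per-level outcome-category counts equal
#' `level_sizes` exactly: each level-l category is assigned a parent
#' among the level-(l-1) categories round-robin, and per-level local ids
#' are encoded in as many base-36 characters as needed.
#'
#' @param level_sizes integer vector of category counts per level,
#'   coarsest first, with non-decreasing values.
#' @param name scheme name.
#' @param seed unused at present (structure is deterministic); kept for
#'   interface stability.
#' @return list with `scheme` (a [scheme_spec()]) and `codes` (character
#'   vector of all full-depth canonical codes).
#' @export
generate_scheme <- function(level_sizes, name = "SYNTH", seed = 1L) {
  level_sizes <- as.integer(level_sizes)
  if (length(level_sizes) < 1L || any(level_sizes < 1L)) {
    stop_data("level_sizes must be positive")
  }
  if (any(diff(level_sizes) < 0L)) {
    stop_data("level_sizes must be non-decreasing")
  }
  widths <- integer(length(level_sizes))
  labels <- vector("list", length(level_sizes))
  prev <- ""
  for (l in seq_along(level_sizes)) {
    nl <- level_sizes[l]
    parents <- if (l == 1L) "" else labels[[l - 1L]]
    parent_of <- parents[((seq_len(nl) - 1L) %% length(parents)) + 1L]
    child_rank <- stats::ave(seq_len(nl), parent_of, FUN = seq_along)
    max_children <- max(child_rank)
    widths[l] <- max(1L, ceiling(log(max_children + 1L, base = 36)))
    local <- vapply(child_rank - 1L, encode_base36, character(1),
                    width = widths[l])
    labels[[l]] <- paste0(parent_of, local)
  }
  scheme <- scheme_spec(name, levels = as.list(cumsum(widths)),
                        placeholder = "#",
                        alphabet = paste(SYNTH_ALPHABET, collapse = ""))
  list(scheme = scheme, codes = labels[[length(labels)]])
}

encode_base36 <- function(x, width) {
  digs <- character(width)
  for (i in seq_len(width)) {
    digs[width - i + 1L] <- SYNTH_ALPHABET[(x %% 36L) + 1L]
    x <- x %/% 36L
  }
  paste(digs, collapse = "")
}

#' Specification of a synthetic job-description corpus
#'
#' The stated world the generator emulates: each code owns a private
#' vocabulary per input class; entries draw code tokens with a
#' `noise_rate` chance of replacement from a shared noise vocabulary;
#' class sizes follow a bounded power law (`imbalance` = Zipf exponent; 0
#' gives near-balance, 1 reproduces the singleton-to-huge-class shape of
#' real cohorts); `incomplete_rate` of the entries get a placeholder
#' suffix on their gold code; per-class word counts have median
#' `words_median` (1-3 in real cohorts).
#'
#' @param scheme a [scheme_spec()].
#' @param codes character vector of full-depth codes to draw from.
#' @param n_entries number of job episodes.
#' @param input_classes names of the free-text input classes.
#' @param words_median target median words per class (>= 1).
#' @param vocab_per_code tokens per code per input class.
#' @param noise_vocab size of the shared noise vocabulary.
#' @param noise_rate probability a token is replaced by noise.
#' @param imbalance Zipf exponent for class sizes.
#' @param incomplete_rate fraction of entries with placeholder-incomplete
#'   gold codes.
#' @param seed integer seed.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(scheme, codes, n_entries = 2000L,
                        input_classes = c("occupation", "sector"),
                        words_median = 2, vocab_per_code = 6L,
                        noise_vocab = 50L, noise_rate = 0.1,
                        imbalance = 1, incomplete_rate = 0.05, seed = 1L) {
  stopifnot(inherits(scheme, "scheme_spec"), length(codes) >= 2L,
            n_entries >= length(codes), words_median >= 1,
            noise_rate >= 0, noise_rate <= 1,
            incomplete_rate >= 0, incomplete_rate <= 1)
  structure(list(scheme = scheme, codes = codes,
                 n_entries = as.integer(n_entries),
                 input_classes = input_classes,
                 words_median = words_median,
                 vocab_per_code = as.integer(vocab_per_code),
                 noise_vocab = as.integer(noise_vocab),
                 noise_rate = noise_rate, imbalance = imbalance,
                 incomplete_rate = incomplete_rate, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Canonical clean recovery world
#'
#' The configuration used for end-to-end pipeline recovery checks: a
#' noise-free, balanced, fully-coded corpus of `n_codes` codes with
#' `examples_per_code` episodes each and a compact per-class vocabulary
#' (2 tokens per code per input class). The compact vocabulary matters:
#' the boosted-tree coder's fixed split penalty (gamma = 1.5) is an
#' absolute loss-reduction threshold, so at desk scale every token needs
#' enough occurrences for its split to clear it — see the methods
#' vignette for the scale analysis.
#'
#' @param n_codes number of codes (level-1 groups are `n_codes / 4`).
#' @param examples_per_code episodes per code.
#' @param seed integer seed.
#' @return list with `scheme`, `codes` and `spec` (a [corpus_spec()]).
#' @export
recovery_corpus_spec <- function(n_codes = 20L, examples_per_code = 50L,
                                 seed = 1L) {
  gen <- generate_scheme(c(max(2L, n_codes %/% 4L), n_codes),
                         name = "SYNTH-RECOVERY", seed = seed)
  spec <- corpus_spec(gen$scheme, gen$codes,
                      n_entries = n_codes * examples_per_code,
                      input_classes = c("occupation", "sector"),
                      vocab_per_code = 2L, noise_rate = 0, imbalance = 0,
                      incomplete_rate = 0, seed = seed)
  list(scheme = gen$scheme, codes = gen$codes, spec = spec)
}

#' Generate a synthetic corpus and its coding index
#'
#' @param spec a [corpus_spec()].
#' @return list with `records` (data frame: `entry_id`, one column per
#'   input class, `gold`) and `index` (one clean canonical description
#'   per code).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    codes <- spec$codes
    ncls <- length(codes)
    w <- seq_len(ncls)^(-spec$imbalance)
    sizes <- largest_remainder(spec$n_entries, w / sum(w))
    sizes <- pmax(sizes, 1L)
    while (sum(sizes) > spec$n_entries) {
      i <- which.max(sizes)
      sizes[i] <- sizes[i] - 1L
    }
    gold_idx <- rep.int(sample.int(ncls), sizes)  # shuffle size ranks over codes
    n <- length(gold_idx)

    noise_words <- sprintf("zq%03d", seq_len(spec$noise_vocab))
    # per class+code private vocabulary; tokens end in a digit so that
    # stemming is the identity on them
    vocab <- lapply(seq_along(spec$input_classes), function(ci) {
      lapply(seq_len(ncls), function(k) {
        sprintf("t%d%s w%d", ci, tolower(codes[k]), seq_len(spec$vocab_per_code))
      })
    })
    vocab <- lapply(vocab, function(vc) {
      lapply(vc, function(v) gsub(" ", "x", v, fixed = TRUE))
    })

    lambda <- spec$words_median - 1
    records <- data.frame(entry_id = sprintf("e%06d", seq_len(n)))
    for (ci in seq_along(spec$input_classes)) {
      texts <- character(n)
      for (i in seq_len(n)) {
        nw <- 1L + rpois(1L, lambda)
        toks <- sample(vocab[[ci]][[gold_idx[i]]], nw, replace = TRUE)
        repl <- runif(nw) < spec$noise_rate
        if (any(repl)) {
          toks[repl] <- sample(noise_words, sum(repl), replace = TRUE)
        }
        texts[i] <- paste(toks, collapse = " ")
      }
      records[[spec$input_classes[ci]]] <- texts
    }
    gold <- codes[gold_idx]
    if (spec$incomplete_rate > 0) {
      sc <- spec$scheme
      cut <- sc$depth[max(1L, n_levels(sc) - 1L)]
      inc <- runif(n) < spec$incomplete_rate
      gold[inc] <- paste0(substr(gold[inc], 1L, cut),
                          strrep(sc$placeholder, sc$full_length - cut))
    }
    records$gold <- gold

    index <- data.frame(entry_id = sprintf("idx%04d", seq_len(ncls)))
    for (ci in seq_along(spec$input_classes)) {
      index[[spec$input_classes[ci]]] <- vapply(seq_len(ncls), function(k) {
        paste(vocab[[ci]][[k]][seq_len(min(3L, spec$vocab_per_code))],
              collapse = " ")
      }, character(1))
    }
    index$gold <- codes

    list(records = records, index = index)
  })
}

largest_remainder <- function(n, fractions) {
  base <- floor(n * fractions)
  left <- n - sum(base)
  if (left > 0) {
    bump <- order(n * fractions - base, decreasing = TRUE)[seq_len(left)]
    base[bump] <- base[bump] + 1
  }
  as.integer(base)
}

#' Generate a synthetic continuous JEM
#'
#' A fraction of the codes receives exposure indices drawn uniformly from
#' the given ranges; all other codes are entered with zero exposure,
#' reproducing matrices in which the large majority of codes carries no
#' exposure (real exposed-episode shares run a few percent).
#'
#' @param codes occupation codes to cover.
#' @param exposed_fraction fraction of codes with non-zero exposure.
#' @param prob_range,intensity_range,freq_range index ranges (probability
#'   and frequency in percent).
#' @param sector_codes optional: build a pair-keyed matrix over
#'   `codes` x `sector_codes`.
#' @param seed integer seed.
#' @return a [continuous_jem()].
#' @export
generate_continuous_jem <- function(codes, exposed_fraction = 0.1,
                                    prob_range = c(5, 100),
                                    intensity_range = c(0.1, 10),
                                    freq_range = c(5, 100),
                                    sector_codes = NULL, seed = 1L) {
  stopifnot(exposed_fraction >= 0, exposed_fraction <= 1)
  with_seed(seed, {
    keys <- if (is.null(sector_codes)) {
      data.frame(occupation = codes)
    } else {
      expand.grid(occupation = codes, sector = sector_codes,
                  stringsAsFactors = FALSE)[, c("occupation", "sector")]
    }
    m <- nrow(keys)
    exposed <- runif(m) < exposed_fraction
    keys$probability <- ifelse(exposed,
                               runif(m, prob_range[1], prob_range[2]), 0)
    keys$intensity <- ifelse(exposed,
                             runif(m, intensity_range[1], intensity_range[2]),
                             0)
    keys$frequency <- ifelse(exposed,
                             runif(m, freq_range[1], freq_range[2]), 0)
    continuous_jem(keys)
  })
}

#' Generate a synthetic ordinal JEM
#'
#' `exposed_fraction` of the codes become exposed: each agent of an
#' exposed code is independently exposed with probability
#' `agent_exposed_prob` (at least one agent is forced), at level 2 with
#' probability `high_prob`, otherwise level 1. Unexposed codes are
#' all-zero for every agent.
#'
#' @param codes occupation codes to cover.
#' @param agents agent names, or a count (named `agent01`...).
#' @param exposed_fraction fraction of exposed codes.
#' @param agent_exposed_prob per-agent exposure probability within an
#'   exposed code.
#' @param high_prob probability an exposed agent is level 2 rather than 1.
#' @param seed integer seed.
#' @return an [ordinal_jem()].
#' @export
generate_ordinal_jem <- function(codes, agents = 12L, exposed_fraction = 0.1,
                                 agent_exposed_prob = 0.5, high_prob = 0.3,
                                 seed = 1L) {
  if (is.numeric(agents)) agents <- sprintf("agent%02d", seq_len(agents))
  if (length(agents) == 0L) stop_data("agent list must be non-empty")
  with_seed(seed, {
    m <- length(codes)
    exposed <- runif(m) < exposed_fraction
    out <- data.frame(occupation = codes)
    lv <- matrix(0L, nrow = m, ncol = length(agents))
    for (i in which(exposed)) {
      on <- runif(length(agents)) < agent_exposed_prob
      if (!any(on)) on[sample.int(length(agents), 1L)] <- TRUE
      lv[i, on] <- ifelse(runif(sum(on)) < high_prob, 2L, 1L)
    }
    for (a in seq_along(agents)) out[[agents[a]]] <- lv[, a]
    ordinal_jem(out, agents)
  })
}
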