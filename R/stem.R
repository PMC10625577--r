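# English Snowball ("Porter2") stemmer, pure R.
#
# Needed because job-description tokens are stemmed before embedding and no
# stemmer ships with the target R stack.  Follows the published algorithm:
# regions R1/R2, y-marking, steps 0-5 with the standard exception lists.
# Operates on lowercase tokens; non-ASCII characters are treated as
# consonants, matching the reference implementation's behaviour on ASCII
# input (the only input the normalizer produces for English).

STEM_VOWELS <- c("a", "e", "i", "o", "u", "y")
STEM_DOUBLES <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
STEM_LI_END <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

STEM_EXC1 <- c(skis = "ski", skies = "sky", dying = "die", lying = "lie",
               tying = "tie", idly = "idl", gently = "gentl", ugly = "ugli",
               early = "earli", only = "onli", singly = "singl",
               sky = "sky", news = "news", howe = "howe", atlas = "atlas",
               cosmos = "cosmos", bias = "bias", andes = "andes")

STEM_EXC2 <- c("inning", "outing", "canning", "herring", "earring",
               "proceed", "exceed", "succeed")

is_vowel <- function(ch) ch %in% STEM_VOWELS

ends_with <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw >= ns && substr(w, nw - ns + 1L, nw) == suf
}

chop <- function(w, n) substr(w, 1L, nchar(w) - n)

# first position (1-based) of region R1 / R2 content
stem_regions <- function(w) {
  n <- nchar(w)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  r1 <- n + 1L
  for (pre in c("gener", "commun", "arsen")) {
    if (startsWith(w, pre)) {
      r1 <- nchar(pre) + 1L
      break
    }
  }
  if (r1 == n + 1L) {
    i <- 2L
    while (i <= n) {
      if (!is_vowel(ch[i]) && is_vowel(ch[i - 1L])) {
        r1 <- i + 1L
        break
      }
      i <- i + 1L
    }
  }
  r2 <- n + 1L
  if (r1 <= n) {
    i <- r1 + 1L
    while (i <= n) {
      if (!is_vowel(ch[i]) && is_vowel(ch[i - 1L])) {
        r2 <- i + 1L
        break
      }
      i <- i + 1L
    }
  }
  c(r1 = r1, r2 = r2)
}

# suffix of length ns starts inside region beginning at rstart?
in_region <- function(w, ns, rstart) nchar(w) - ns + 1L >= rstart

# word ends in a short syllable?
ends_short_syllable <- function(w) {
  n <- nchar(w)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  if (n == 2L) {
    return(is_vowel(ch[1]) && !is_vowel(ch[2]))
  }
  if (n >= 3L) {
    c3 <- ch[n]
    c2 <- ch[n - 1L]
    c1 <- ch[n - 2L]
    return(!is_vowel(c3) && !(c3 %in% c("w", "x", "Y")) &&
             is_vowel(c2) && !is_vowel(c1))
  }
  FALSE
}

has_vowel <- function(w) {
  any(is_vowel(strsplit(w, "", fixed = TRUE)[[1]]))
}

stem_en_word <- function(w) {
  if (startsWith(w, "'")) w <- substr(w, 2L, nchar(w))
  if (w %in% names(STEM_EXC1)) return(unname(STEM_EXC1[w]))
  if (nchar(w) <= 2L) return(w)

  # mark consonant y as Y
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  if (ch[1] == "y") ch[1] <- "Y"
  if (length(ch) > 1L) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && is_vowel(ch[i - 1L])) ch[i] <- "Y"
    }
  }
  w <- paste(ch, collapse = "")
  reg <- stem_regions(w)
  r1 <- reg[["r1"]]
  r2 <- reg[["r2"]]

  # step 0: detach apostrophe suffixes
  for (suf in c("'s'", "'s", "'")) {
    if (ends_with(w, suf)) {
      w <- chop(w, nchar(suf))
      break
    }
  }

  # step 1a
  if (ends_with(w, "sses")) {
    w <- paste0(chop(w, 4L), "ss")
  } else if (ends_with(w, "ied") || ends_with(w, "ies")) {
    w <- if (nchar(w) > 4L) paste0(chop(w, 3L), "i") else paste0(chop(w, 3L), "ie")
  } else if (ends_with(w, "us") || ends_with(w, "ss")) {
    # leave as is
  } else if (ends_with(w, "s")) {
    stem_part <- chop(w, 1L)
    if (nchar(stem_part) >= 2L && has_vowel(chop(stem_part, 1L))) {
      w <- stem_part
    }
  }

  if (w %in% STEM_EXC2) return(w)

  # step 1b
  done1b <- FALSE
  for (suf in c("eedly", "eed")) {
    if (ends_with(w, suf)) {
      if (in_region(w, nchar(suf), r1)) w <- paste0(chop(w, nchar(suf)), "ee")
      done1b <- TRUE
      break
    }
  }
  if (!done1b) {
    for (suf in c("ingly", "edly", "ing", "ed")) {
      if (ends_with(w, suf)) {
        stem_part <- chop(w, nchar(suf))
        if (has_vowel(stem_part)) {
          w <- stem_part
          if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
            w <- paste0(w, "e")
          } else if (ends_with(w, substr(w, nchar(w) - 1L, nchar(w))) &&
                     substr(w, nchar(w) - 1L, nchar(w)) %in% STEM_DOUBLES) {
            w <- chop(w, 1L)
          } else if (stem_regions_is_short(w, r1)) {
            w <- paste0(w, "e")
          }
        }
        break
      }
    }
  }

  # step 1c: y -> i after a consonant that is not word-initial
  n <- nchar(w)
  if (n > 2L) {
    last <- substr(w, n, n)
    prev <- substr(w, n - 1L, n - 1L)
    if ((last == "y" || last == "Y") && !is_vowel(prev)) {
      w <- paste0(chop(w, 1L), "i")
    }
  }

  # step 2 (longest among; condition: suffix in R1)
  s2 <- list(
    c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
    c("ousness", "ous"), c("iveness", "ive"), c("tional", "tion"),
    c("biliti", "ble"), c("lessli", "less"), c("entli", "ent"),
    c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
    c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
    c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
    c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
    c("ogi", "og"), c("bli", "ble"), c("li", "")
  )
  for (p in s2) {
    suf <- p[1]
    if (ends_with(w, suf)) {
      if (in_region(w, nchar(suf), r1)) {
        if (suf == "ogi") {
          if (ends_with(chop(w, 3L), "l")) w <- paste0(chop(w, 3L), "og")
        } else if (suf == "li") {
          if (substr(w, nchar(w) - 2L, nchar(w) - 2L) %in% STEM_LI_END) {
            w <- chop(w, 2L)
          }
        } else {
          w <- paste0(chop(w, nchar(suf)), p[2])
        }
      }
      break
    }
  }

  # step 3 (condition: suffix in R1; "ative" additionally in R2)
  s3 <- list(
    c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
    c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (p in s3) {
    suf <- p[1]
    if (ends_with(w, suf)) {
      if (in_region(w, nchar(suf), r1)) {
        if (suf == "ative") {
          if (in_region(w, 5L, r2)) w <- chop(w, 5L)
        } else {
          w <- paste0(chop(w, nchar(suf)), p[2])
        }
      }
      break
    }
  }

  # step 4 (condition: suffix in R2)
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  for (suf in s4) {
    if (ends_with(w, suf)) {
      if (in_region(w, nchar(suf), r2)) {
        if (suf == "ion") {
          prev <- substr(w, nchar(w) - 3L, nchar(w) - 3L)
          if (prev %in% c("s", "t")) w <- chop(w, 3L)
        } else {
          w <- chop(w, nchar(suf))
        }
      }
      break
    }
  }

  # step 5
  n <- nchar(w)
  if (ends_with(w, "e")) {
    if (in_region(w, 1L, r2) ||
        (in_region(w, 1L, r1) && !ends_short_syllable(chop(w, 1L)))) {
      w <- chop(w, 1L)
    }
  } else if (ends_with(w, "ll") && in_region(w, 1L, r2)) {
    w <- chop(w, 1L)
  }

  gsub("Y", "y", w, fixed = TRUE)
}

# "word is short": R1 is null and the word ends in a short syllable
stem_regions_is_short <- function(w, r1) {
  r1 > nchar(w) && ends_short_syllable(w)
}

#' Stem English tokens (Snowball)
#'
#' Reduces lowercase English tokens to their root form with the English
#' Snowball stemming algorithm (the revision of the classic Porter
#' stemmer), e.g. `"service"` to `"servic"` and `"nurse"` to `"nurs"`.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length.
#' @export
#' @examples
#' stem_tokens(c("service", "employee", "nurse"))
stem_tokens <- function(tokens) {
  vapply(tokens, stem_en_word, character(1), USE.NAMES = FALSE)
}
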