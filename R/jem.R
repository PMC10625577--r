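#' Continuous job-exposure matrix
#'
#' A lookup table from occupation code (optionally combined with an
#' activity-sector code and a calendar period) to three exposure indices:
#' probability (percent of exposed workers), intensity (mean exposure dose
#' during tasks, arbitrary units) and frequency (percent of working time).
#'
#' @param entries data frame with columns `occupation`, optional `sector`,
#'   optional `period_start`/`period_end` (integer years), `probability`,
#'   `intensity`, `frequency`.
#' @return object of class `continuous_jem`.
#' @export
continuous_jem <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("occupation", "probability", "intensity", "frequency")
  if (!all(need %in% names(entries))) {
    stop_data("continuous JEM needs columns: ", paste(need, collapse = ", "))
  }
  for (cl in c("probability", "frequency")) {
    v <- entries[[cl]]
    if (any(!is.finite(v)) || any(v < 0 | v > 100)) {
      stop_data(cl, " must lie in [0, 100]")
    }
  }
  if (any(entries$intensity < 0)) stop_data("intensity must be >= 0")
  has_sector <- "sector" %in% names(entries)
  has_period <- all(c("period_start", "period_end") %in% names(entries))
  key <- jem_key(entries$occupation,
                 if (has_sector) entries$sector else NULL)
  if (!has_period && anyDuplicated(key)) {
    stop_data("duplicate JEM keys")
  }
  structure(list(entries = entries, key = key, has_sector = has_sector,
                 has_period = has_period),
            class = "continuous_jem")
}

#' Ordinal job-exposure matrix
#'
#' Maps each occupation code to an exposure level per agent: 0 (no
#' exposure), 1 (low) or 2 (high), the convention of general-population
#' matrices covering e.g. 12 generic industrial agents or 9 carcinogens.
#'
#' @param entries data frame with a `occupation` column and one integer
#'   column per agent.
#' @param agents agent column names; default: all non-key columns.
#' @return object of class `ordinal_jem`.
#' @export
ordinal_jem <- function(entries, agents = NULL) {
  stopifnot(is.data.frame(entries), "occupation" %in% names(entries))
  if (is.null(agents)) agents <- setdiff(names(entries), "occupation")
  if (length(agents) == 0L) stop_data("ordinal JEM needs agent columns")
  for (a in agents) {
    v <- entries[[a]]
    if (is.null(v)) stop_data("agent column missing: ", a)
    if (!all(v %in% 0:2)) stop_data("agent ", a, " has levels outside 0..2")
  }
  if (anyDuplicated(entries$occupation)) stop_data("duplicate JEM keys")
  structure(list(entries = entries, agents = agents,
                 key = as.character(entries$occupation)),
            class = "ordinal_jem")
}

jem_key <- function(occupation, sector = NULL) {
  if (is.null(sector)) {
    as.character(occupation)
  } else {
    paste(occupation, sector, sep = "\r")
  }
}

#' @export
print.continuous_jem <- function(x, ...) {
  cat(sprintf("<continuous_jem> %d entries%s%s\n", nrow(x$entries),
              if (x$has_sector) ", keyed by occupation+sector" else "",
              if (x$has_period) ", with calendar periods" else ""))
  invisible(x)
}

#' @export
print.ordinal_jem <- function(x, ...) {
  cat(sprintf("<ordinal_jem> %d entries, %d agents\n", nrow(x$entries),
              length(x$agents)))
  invisible(x)
}

#' Read a continuous JEM from CSV
#' @param path CSV with columns `occupation`, optional `sector`,
#'   optional `period_start`/`period_end`, `probability`, `intensity`,
#'   `frequency`.
#' @return a [continuous_jem()].
#' @export
read_continuous_jem <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  for (cl in intersect(c("occupation", "sector"), names(df))) {
    df[[cl]] <- as.character(df[[cl]])
  }
  continuous_jem(df)
}

#' Read an ordinal JEM from CSV
#' @param path CSV with a `occupation` column and one column per agent.
#' @return an [ordinal_jem()].
#' @export
read_ordinal_jem <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  df$occupation <- as.character(df$occupation)
  ordinal_jem(df)
}

#' Look up exposure for coded job episodes
#'
#' Exact-key lookup. Under the default `"zero"` policy a code absent from
#' the matrix yields all-zero exposure and is counted in the `unmatched`
#' attribute of the result; under `"strict"` it is an error. A period
#' passed against a period-less matrix is ignored with a warning; a
#' period-resolved matrix picks the row whose `[period_start,
#' period_end]` contains the requested year.
#'
#' @param jem a [continuous_jem()] or [ordinal_jem()].
#' @param occupation character vector of complete occupation codes.
#' @param sector optional character vector of sector codes (pair-keyed
#'   continuous matrices).
#' @param period optional single year.
#' @param policy `"zero"` or `"strict"`.
#' @return data frame of indices (continuous: `probability`, `intensity`,
#'   `frequency`; ordinal: one column per agent), one row per input, with
#'   attribute `unmatched` (count of keys not in the matrix).
#' @export
jem_lookup <- function(jem, occupation, sector = NULL, period = NULL,
                       policy = c("zero", "strict")) {
  policy <- match.arg(policy)
  UseMethod("jem_lookup")
}

#' @export
jem_lookup.continuous_jem <- function(jem, occupation, sector = NULL,
                                      period = NULL,
                                      policy = c("zero", "strict")) {
  policy <- match.arg(policy)
  if (jem$has_sector && is.null(sector)) {
    stop_data("this JEM is keyed by occupation+sector; supply `sector`")
  }
  entries <- jem$entries
  keys <- jem$key
  if (!is.null(period)) {
    if (!jem$has_period) {
      warning("JEM has no calendar periods; `period` ignored")
    } else {
      sel <- entries$period_start <= period & entries$period_end >= period
      entries <- entries[sel, , drop = FALSE]
      keys <- keys[sel]
      if (anyDuplicated(keys)) stop_data("duplicate JEM keys within period")
    }
  } else if (jem$has_period) {
    stop_data("this JEM is period-resolved; supply `period`")
  }
  want <- jem_key(occupation, if (jem$has_sector) sector else NULL)
  i <- match(want, keys)
  miss <- is.na(i)
  if (any(miss) && policy == "strict") {
    stop_data("code(s) absent from JEM: ",
              paste(head(unique(occupation[miss]), 5), collapse = ", "))
  }
  out <- data.frame(probability = ifelse(miss, 0, entries$probability[i]),
                    intensity = ifelse(miss, 0, entries$intensity[i]),
                    frequency = ifelse(miss, 0, entries$frequency[i]))
  attr(out, "unmatched") <- sum(miss)
  out
}

#' @export
jem_lookup.ordinal_jem <- function(jem, occupation, sector = NULL,
                                   period = NULL,
                                   policy = c("zero", "strict")) {
  policy <- match.arg(policy)
  if (!is.null(period)) warning("JEM has no calendar periods; `period` ignored")
  i <- match(as.character(occupation), jem$key)
  miss <- is.na(i)
  if (any(miss) && policy == "strict") {
    stop_data("code(s) absent from JEM: ",
              paste(head(unique(occupation[miss]), 5), collapse = ", "))
  }
  out <- jem$entries[ifelse(miss, 1L, i), jem$agents, drop = FALSE]
  out[miss, ] <- 0L
  rownames(out) <- NULL
  attr(out, "unmatched") <- sum(miss)
  out
}

#' Total exposure from continuous indices
#'
#' Product of the three indices with probability and frequency taken as
#' proportions: `(probability/100) * intensity * (frequency/100)`. Zero in
#' any index gives zero total exposure.
#'
#' @param idx data frame with `probability`, `intensity`, `frequency`
#'   columns (as returned by [jem_lookup()]).
#' @return numeric vector of non-negative totals.
#' @export
total_exposure <- function(idx) {
  stopifnot(all(c("probability", "intensity", "frequency") %in% names(idx)))
  (idx$probability / 100) * idx$intensity * (idx$frequency / 100)
}

#' Dichotomize total exposure
#'
#' An episode counts as exposed iff its total exposure is strictly greater
#' than 0.
#'
#' @param total numeric vector of non-negative totals.
#' @return character vector, `"exposed"` or `"not_exposed"`.
#' @export
dichotomize <- function(total) {
  if (any(total < 0)) stop_data("total exposure must be non-negative")
  ifelse(total > 0, "exposed", "not_exposed")
}

#' Gold-exposed subset selector
#'
#' Which episodes are exposed according to their gold-standard codes:
#' positive total exposure (continuous JEM) or any agent level above 0
#' (ordinal JEM). Evaluating on this subset counters the high chance
#' agreement of all-zero assignments when most codes carry no exposure.
#'
#' @param jem a JEM object.
#' @param occupation gold occupation codes.
#' @param sector optional gold sector codes.
#' @param period optional year.
#' @return logical vector.
#' @export
gold_exposed <- function(jem, occupation, sector = NULL, period = NULL) {
  lk <- jem_lookup(jem, occupation, sector = sector, period = period)
  if (inherits(jem, "continuous_jem")) {
    total_exposure(lk) > 0
  } else {
    rowSums(as.matrix(lk)) > 0
  }
}

#' Exposure-assessment evaluation against a continuous JEM
#'
#' Applies the matrix to gold and predicted codes and compares the
#' resulting total exposures: exact-match accuracy and Cohen's kappa on
#' the totals (each distinct total treated as a category), accuracy/kappa
#' of the dichotomous exposed status, and the tie-corrected Kendall rank
#' correlation (tau-b, normal-approximation two-sided p) of the totals.
#' Every metric is reported for all episodes and for the subset exposed
#' under the gold codes. With per-record confidence scores, accuracies
#' are additionally binned in 5% confidence intervals; for pair-coded
#' records pass both scores and the minimum is used, mirroring an
#' auto-coding rule that demands both codes clear the threshold.
#'
#' @param gold,pred data frames with `occupation` (and `sector` if the
#'   matrix is pair-keyed) columns, or bare character vectors of
#'   occupation codes; aligned by row.
#' @param jem a [continuous_jem()].
#' @param confidences optional numeric vector, or 2-column matrix/data
#'   frame of the two codes' confidences (row minimum used).
#' @param period optional year for period-resolved matrices.
#' @return list of class `jem_eval` with the metric blocks described
#'   above, plus `n_all`, `n_exposed` and unmatched-lookup counters.
#' @export
evaluate_continuous <- function(gold, pred, jem, confidences = NULL,
                                period = NULL) {
  g <- as_code_table(gold, jem$has_sector)
  p <- as_code_table(pred, jem$has_sector)
  if (nrow(g) != nrow(p)) stop_data("gold and pred are misaligned")
  lg <- jem_lookup(jem, g$occupation, g$sector, period = period)
  lp <- jem_lookup(jem, p$occupation, p$sector, period = period)
  tg <- total_exposure(lg)
  tp <- total_exposure(lp)
  exposed <- tg > 0

  conf <- NULL
  if (!is.null(confidences)) {
    conf <- if (is.null(dim(confidences))) {
      as.numeric(confidences)
    } else {
      do.call(pmin, as.data.frame(confidences))
    }
    if (length(conf) != nrow(g)) stop_data("confidences misaligned")
  }

  block <- function(sel) {
    tg <- tg[sel]
    tp <- tp[sel]
    kt <- if (length(unique(tg)) < 2 || length(unique(tp)) < 2) {
      list(tau = NA_real_, p = NA_real_)
    } else {
      kendall_tau(tg, tp)
    }
    list(n = sum(sel),
         accuracy = if (any(sel)) accuracy(tp, tg) else NA_real_,
         kappa = if (any(sel)) cohens_kappa(tp, tg) else NA_real_,
         dichotomous_accuracy = if (any(sel))
           accuracy(dichotomize(tp), dichotomize(tg)) else NA_real_,
         dichotomous_kappa = if (any(sel))
           cohens_kappa(dichotomize(tp), dichotomize(tg)) else NA_real_,
         kendall_tau = kt$tau, kendall_p = kt$p,
         bins = if (!is.null(conf)) {
           bin_by_confidence(conf[sel], (tp == tg))
         })
  }
  structure(list(kind = "continuous",
                 n_all = nrow(g), n_exposed = sum(exposed),
                 unmatched_gold = attr(lg, "unmatched"),
                 unmatched_pred = attr(lp, "unmatched"),
                 all = block(rep(TRUE, nrow(g))),
                 exposed = block(exposed)),
            class = "jem_eval")
}

#' Exposure-assessment evaluation against an ordinal JEM
#'
#' An episode's assessment is correct only if the predicted code
#' reproduces the gold exposure level for every agent (one wrong agent
#' fails the episode). Reported: overall all-agent accuracy and kappa (on
#' full agent-level profiles treated as categories), per-agent accuracy
#' and kappa, per-level (0/1/2) accuracy within each agent, each for all
#' episodes and for the gold-exposed subset.
#'
#' @param gold,pred character vectors of occupation codes, aligned.
#' @param jem an [ordinal_jem()].
#' @param confidences optional numeric vector of the codes' confidence
#'   scores for 5%-binned accuracies.
#' @return list of class `jem_eval`.
#' @export
evaluate_ordinal <- function(gold, pred, jem, confidences = NULL) {
  gold <- as.character(gold)
  pred <- as.character(pred)
  if (length(gold) != length(pred)) stop_data("gold and pred are misaligned")
  lg <- jem_lookup(jem, gold)
  lp <- jem_lookup(jem, pred)
  G <- as.matrix(lg)
  P <- as.matrix(lp)
  exposed <- rowSums(G) > 0
  if (!is.null(confidences) && length(confidences) != length(gold)) {
    stop_data("confidences misaligned")
  }

  block <- function(sel) {
    G <- G[sel, , drop = FALSE]
    P <- P[sel, , drop = FALSE]
    if (!any(sel)) return(list(n = 0L))
    all_match <- rowSums(G == P) == ncol(G)
    profile_g <- apply(G, 1, paste, collapse = "/")
    profile_p <- apply(P, 1, paste, collapse = "/")
    per_agent <- do.call(rbind, lapply(jem$agents, function(a) {
      data.frame(agent = a,
                 accuracy = accuracy(P[, a], G[, a]),
                 kappa = cohens_kappa(P[, a], G[, a]))
    }))
    per_level <- do.call(rbind, lapply(jem$agents, function(a) {
      do.call(rbind, lapply(0:2, function(lv) {
        i <- G[, a] == lv
        data.frame(agent = a, level = lv, n = sum(i),
                   accuracy = if (any(i)) 100 * mean(P[i, a] == lv)
                              else NA_real_)
      }))
    }))
    list(n = sum(sel),
         accuracy = 100 * mean(all_match),
         kappa = cohens_kappa(profile_p, profile_g),
         per_agent = per_agent,
         per_level = per_level,
         bins = if (!is.null(confidences)) {
           bin_by_confidence(confidences[sel], all_match)
         })
  }
  structure(list(kind = "ordinal",
                 n_all = length(gold), n_exposed = sum(exposed),
                 unmatched_gold = attr(lg, "unmatched"),
                 unmatched_pred = attr(lp, "unmatched"),
                 all = block(rep(TRUE, length(gold))),
                 exposed = block(exposed)),
            class = "jem_eval")
}

#' @export
print.jem_eval <- function(x, ...) {
  cat(sprintf("<jem_eval> %s: n=%d (exposed %d); accuracy all %.2f%%, exposed %s\n",
              x$kind, x$n_all, x$n_exposed, x$all$accuracy,
              if (is.null(x$exposed$accuracy)) "-" else
                sprintf("%.2f%%", x$exposed$accuracy)))
  invisible(x)
}

as_code_table <- function(x, need_sector) {
  if (is.data.frame(x)) {
    if (!"occupation" %in% names(x)) stop_data("code table needs `occupation`")
    if (need_sector && !"sector" %in% names(x)) {
      stop_data("pair-keyed JEM needs a `sector` column")
    }
    data.frame(occupation = as.character(x$occupation),
               sector = if ("sector" %in% names(x))
                 as.character(x$sector) else NA_character_)
  } else {
    if (need_sector) {
      stop_data("pair-keyed JEM needs a `sector` column; pass a data frame")
    }
    data.frame(occupation = as.character(x), sector = NA_character_)
  }
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Tie-corrected Kendall tau with a two-sided p-value from the normal
#' approximation; appropriate for exposure totals that are massively tied
#' at zero. Errors when either side is constant (tau undefined).
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return list with `tau` and `p`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_data("x and y must be of equal length >= 2")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_data("tau undefined: constant input")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}
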