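#' Coding accuracy in percent
#'
#' The share of predictions exactly equal to the gold standard (string
#' equality of canonical codes or level labels), times 100.
#'
#' @param predicted,gold equal-length character vectors.
#' @return percent in `[0, 100]`.
#' @export
accuracy <- function(predicted, gold) {
  if (length(predicted) != length(gold) || length(gold) == 0L) {
    stop_data("predicted and gold must be non-empty and of equal length")
  }
  100 * mean(as.character(predicted) == as.character(gold))
}

#' Cohen's kappa between two coders
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)`, where `Po` is the
#' observed agreement proportion and `Pe` the chance agreement: the sum
#' over labels of the product of each coder's marginal proportion for that
#' label. In the degenerate case where both coders use a single identical
#' label (`Pe = 1`, `Po = 1`) the function returns exactly 1.
#'
#' @param predicted,gold equal-length character vectors of labels.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(predicted, gold) {
  if (length(predicted) != length(gold) || length(gold) == 0L) {
    stop_data("predicted and gold must be non-empty and of equal length")
  }
  predicted <- as.character(predicted)
  gold <- as.character(gold)
  po <- mean(predicted == gold)
  labels <- union(predicted, gold)
  pa <- tabulate(match(predicted, labels), length(labels)) / length(predicted)
  pb <- tabulate(match(gold, labels), length(labels)) / length(gold)
  pe <- sum(pa * pb)
  if (pe >= 1 - 1e-15) return(1)
  (po - pe) / (1 - pe)
}

#' Accuracy and kappa per coding level
#'
#' Truncates predictions and gold codes to each level of the scheme and
#' reports the number of outcome categories (distinct gold labels),
#' accuracy and Cohen's kappa at that level. One full-depth model is
#' evaluated per scheme; coarser levels are prefix truncations of its
#' predictions, so accuracy is non-increasing in level by construction.
#'
#' @param predicted,gold character vectors of complete code strings (or
#'   `occ_codes`).
#' @param scheme a [scheme_spec()].
#' @return data frame with columns `level`, `outcome_categories`,
#'   `accuracy`, `kappa`, `n`.
#' @export
per_level_metrics <- function(predicted, gold, scheme) {
  pred <- as_occ_codes(predicted, scheme)
  gld <- as_occ_codes(gold, scheme)
  if (length(pred) != length(gld)) stop_data("length mismatch")
  do.call(rbind, lapply(seq_len(n_levels(scheme)), function(l) {
    pl <- truncate_code(pred, l)
    gl <- truncate_code(gld, l)
    data.frame(level = l,
               outcome_categories = length(unique(gl)),
               accuracy = accuracy(pl, gl),
               kappa = cohens_kappa(pl, gl),
               n = length(gl))
  }))
}

#' Full-code accuracy per major (level-1) group
#'
#' Partitions records by the gold code's level-1 label and reports
#' full-depth accuracy within each non-empty group.
#'
#' @inheritParams per_level_metrics
#' @return data frame with columns `group`, `accuracy`, `n`.
#' @export
per_group_accuracy <- function(predicted, gold, scheme) {
  pred <- as_occ_codes(predicted, scheme)
  gld <- as_occ_codes(gold, scheme)
  if (length(pred) != length(gld)) stop_data("length mismatch")
  grp <- truncate_code(gld, 1L)
  pc <- code_canonical(pred)
  gc <- code_canonical(gld)
  out <- lapply(sort(unique(grp)), function(g) {
    i <- grp == g
    data.frame(group = g, accuracy = accuracy(pc[i], gc[i]), n = sum(i))
  })
  do.call(rbind, out)
}

as_occ_codes <- function(x, scheme) {
  if (inherits(x, "occ_codes")) x else parse_code(scheme, x)
}

#' Levene's test for equality of variances
#'
#' Classic Levene: a one-way ANOVA on the absolute deviations from the
#' group mean. Used to decide between the pooled and the Welch t-test.
#'
#' @param x,y numeric samples.
#' @return list with `statistic`, `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(x, y) {
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  n <- length(z)
  k <- 2L
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[g])^2) / (n - k)
  stat <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
  p <- if (is.finite(stat)) pf(stat, k - 1, n - k, lower.tail = FALSE) else 0
  list(statistic = stat, df1 = k - 1L, df2 = n - k, p.value = p)
}

#' Hedges g standardized mean difference
#'
#' Pooled-SD standardized difference of means with the small-sample bias
#' correction `1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param x,y numeric samples (the sign convention is `mean(x) - mean(y)`).
#' @return numeric effect size.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  d * (1 - 3 / (4 * (n1 + n2) - 9))
}

#' Compare model inter-coder reliability against expert coders
#'
#' For each coding level, compares the distribution of per-pair expert
#' kappas with the per-model kappas: Shapiro-Wilk normality per group,
#' Levene's test across groups, then a pooled independent-sample t-test
#' (`df = n1 + n2 - 2`) when Levene does not reject equal variances at
#' `alpha`, or Welch's t-test when it does. The t statistic is oriented
#' model minus human (positive = models agree more). Hedges g uses the
#' same orientation. Shapiro-Wilk needs at least 3 values; groups of size
#' 2 report `NA` for it.
#'
#' @param human_kappas,model_kappas either numeric vectors (a single
#'   level) or data frames with columns `level` and `kappa`.
#' @param alpha significance level for the Levene decision (default 0.05).
#' @return data frame with one row per level: group means, ranges, sample
#'   SDs (n-1), Shapiro p per group, Levene p, `welch_used`, `t`, `df`
#'   (non-integer for Welch), two-sided `p`, `hedges_g`.
#' @export
compare_humans_model <- function(human_kappas, model_kappas, alpha = 0.05) {
  as_by_level <- function(v) {
    if (is.data.frame(v)) {
      stopifnot(all(c("level", "kappa") %in% names(v)))
      return(split(v$kappa, v$level))
    }
    list(`1` = as.numeric(v))
  }
  h <- as_by_level(human_kappas)
  m <- as_by_level(model_kappas)
  levels <- intersect(names(h), names(m))
  if (length(levels) == 0L) stop_data("no common levels to compare")
  do.call(rbind, lapply(levels, function(lv) {
    compare_two_groups(h[[lv]], m[[lv]], alpha = alpha, level = lv)
  }))
}

compare_two_groups <- function(human, model, alpha = 0.05, level = NA) {
  if (length(human) < 2L || length(model) < 2L) {
    stop_data("insufficient data: each group needs at least 2 values")
  }
  sw <- function(v) {
    if (length(v) < 3L || stats::sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }
  lev <- levene_test(human, model)
  welch <- lev$p.value < alpha
  tt <- t.test(model, human, var.equal = !welch)
  data.frame(
    level = as.integer(level),
    n_human = length(human), n_model = length(model),
    mean_human = mean(human), mean_model = mean(model),
    min_human = min(human), max_human = max(human),
    min_model = min(model), max_model = max(model),
    sd_human = stats::sd(human), sd_model = stats::sd(model),
    shapiro_p_human = sw(human), shapiro_p_model = sw(model),
    levene_p = lev$p.value, welch_used = welch,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, hedges_g = hedges_g(model, human),
    alpha = alpha)
}
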