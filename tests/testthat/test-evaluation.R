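test_that("accuracy is exact-match percent", {
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 75)
  expect_equal(accuracy(letters[1:5], letters[1:5]), 100)
  expect_equal(accuracy(letters[1:5], LETTERS[1:5]), 0)
  expect_error(accuracy("a", c("a", "b")), "equal length")
})

test_that("cohens_kappa matches its definition and handles degeneracy", {
  expect_equal(cohens_kappa(c("a", "b", "a", "b"), c("a", "b", "a", "b")), 1)
  expect_equal(cohens_kappa(c("a", "a", "b", "b"), c("a", "b", "a", "b")), 0)
  # both coders constant on the same label: exactly 1
  expect_identical(cohens_kappa(rep("x", 5), rep("x", 5)), 1)
  # constant but different labels: no agreement, no chance agreement
  expect_equal(cohens_kappa(rep("x", 5), rep("y", 5)), 0)
  # invariance under consistent relabeling
  set.seed(21)
  a <- sample(letters[1:6], 40, replace = TRUE)
  b <- sample(letters[1:6], 40, replace = TRUE)
  perm <- setNames(LETTERS[6:1], letters[1:6])
  expect_equal(cohens_kappa(a, b), cohens_kappa(perm[a], perm[b]))
})

test_that("kappa equals the brute-force Po/Pe oracle on 100 fixtures", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    k <- sample(2:6, 1)
    a <- sample(letters[1:k], n, replace = TRUE)
    b <- sample(letters[1:k], n, replace = TRUE)
    expect_equal(cohens_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("per_level_metrics truncates and scores per level", {
  sc <- builtin_scheme("isco88")
  pred <- c("2221", "2222", "3111", "3112")
  gold <- c("2221", "2223", "3121", "4111")
  m <- per_level_metrics(pred, gold, sc)
  expect_equal(m$level, 1:4)
  expect_equal(m$accuracy[1], 75)             # level 1: 2,2,3,3 vs 2,2,3,4
  expect_equal(m$accuracy[4], 25)
  expect_true(all(diff(m$accuracy) <= 0))     # nesting
  expect_equal(m$outcome_categories, c(3L, 3L, 3L, 4L))
  expect_equal(m$n, rep(4L, 4))
  # full-depth row equals direct accuracy/kappa on canonical codes
  expect_equal(m$accuracy[4], accuracy(pred, gold))
  expect_equal(m$kappa[4], cohens_kappa(pred, gold))
})

test_that("per_group_accuracy partitions by the gold level-1 label", {
  sc <- builtin_scheme("isco88")
  pred <- c("2221", "2222", "3111", "3112", "3113")
  gold <- c("2221", "2222", "3121", "3122", "3113")
  g <- per_group_accuracy(pred, gold, sc)
  expect_equal(g$group, c("2", "3"))
  expect_equal(g$accuracy, c(100, 100 / 3))
  expect_equal(g$n, c(2L, 3L))
  # single group equals overall accuracy
  one <- per_group_accuracy(pred[1:2], gold[1:2], sc)
  expect_equal(one$accuracy, accuracy(pred[1:2], gold[1:2]))
  # brute-force partition oracle on a random fixture
  set.seed(33)
  codes <- sprintf("%d%d%d%d", sample(1:9, 60, TRUE), sample(0:9, 60, TRUE),
                   sample(0:9, 60, TRUE), sample(0:9, 60, TRUE))
  perm <- ifelse(runif(60) < 0.5, codes, sample(codes))
  g2 <- per_group_accuracy(perm, codes, sc)
  for (r in seq_len(nrow(g2))) {
    i <- substr(codes, 1, 1) == g2$group[r]
    expect_equal(g2$accuracy[r], 100 * mean(perm[i] == codes[i]))
  }
})

test_that("human-vs-model comparison picks pooled vs Welch via Levene", {
  human <- c(0.59, 0.62, 0.64, 0.66, 0.67, 0.68, 0.63, 0.65,
             0.70, 0.72, 0.66, 0.69, 0.71, 0.61, 0.76, 0.73)
  model <- c(0.66, 0.73, 0.78, 0.84)
  res <- compare_humans_model(human, model)
  expect_false(res$welch_used)                 # Levene p = 0.22
  expect_equal(res$df, 18)                     # pooled: 16 + 4 - 2
  # textbook pooled-t oracle
  sp2 <- (15 * var(human) + 3 * var(model)) / 18
  t_hand <- (mean(model) - mean(human)) / sqrt(sp2 * (1 / 16 + 1 / 4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$sd_model, sd(model))        # sample SD, n-1

  # unequal variances: Welch path with the textbook df
  x <- c(0.2, 0.25, 0.3, 0.22, 0.28)
  y <- c(0.5, 0.9, 0.1, 0.7)
  res2 <- compare_two_groups(x, y, alpha = 0.5)  # force the Welch branch
  expect_true(res2$welch_used)
  v1 <- var(x) / 5
  v2 <- var(y) / 4
  expect_equal(res2$df, (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 3),
               tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- c(0.1, 0.2, 0.3, 0.4)
  res3 <- compare_humans_model(same, same)
  expect_equal(res3$t, 0)
  expect_equal(res3$p, 1)

  expect_error(compare_humans_model(c(1, 2), 3), "at least 2")
})

test_that("hedges_g applies the small-sample correction", {
  x <- c(0.75, 0.66, 0.84, 0.74)
  y <- c(0.67, 0.63, 0.71, 0.70, 0.65, 0.66)
  n1 <- 4; n2 <- 6
  sp <- sqrt((3 * var(x) + 5 * var(y)) / 8)
  expect_equal(hedges_g(x, y),
               (mean(x) - mean(y)) / sp * (1 - 3 / (4 * 10 - 9)),
               tolerance = 1e-12)
})

test_that("per-level comparison frames align by level", {
  hk <- data.frame(level = rep(1:2, each = 4),
                   kappa = c(0.71, 0.68, 0.74, 0.70, 0.66, 0.63, 0.69, 0.65))
  mk <- data.frame(level = rep(1:2, each = 4),
                   kappa = c(0.75, 0.66, 0.84, 0.74, 0.72, 0.62, 0.81, 0.71))
  res <- compare_humans_model(hk, mk)
  expect_equal(nrow(res), 2L)
  expect_equal(res$df, c(6, 6))
})
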