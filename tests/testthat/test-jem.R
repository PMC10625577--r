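toy_cjem <- function() {
  continuous_jem(data.frame(
    occupation = c("11", "12", "21", "22"),
    probability = c(50, 0, 100, 25),
    intensity = c(2, 0, 1, 4),
    frequency = c(50, 0, 100, 10)))
}

toy_ojem <- function() {
  ordinal_jem(data.frame(
    occupation = c("11", "12", "21", "22"),
    dust = c(0L, 1L, 2L, 0L),
    fumes = c(0L, 0L, 1L, 2L),
    solvents = c(0L, 0L, 0L, 0L)))
}

test_that("lookup returns stored indices, zeros for absent codes", {
  jem <- toy_cjem()
  hit <- jem_lookup(jem, c("11", "21"))
  expect_equal(hit$probability, c(50, 100))
  expect_equal(attr(hit, "unmatched"), 0L)
  miss <- jem_lookup(jem, c("11", "99"))
  expect_equal(unlist(miss[2, ]), c(probability = 0, intensity = 0,
                                    frequency = 0))
  expect_equal(attr(miss, "unmatched"), 1L)
  expect_error(jem_lookup(jem, "99", policy = "strict"), "absent from JEM")
  expect_warning(jem_lookup(jem, "11", period = 1990), "ignored")
  # unmatched counter + matches = total lookups
  got <- jem_lookup(jem, c("11", "99", "21", "98"))
  expect_equal(attr(got, "unmatched") + sum(got$probability > 0 |
                                              got$intensity > 0), 4L)
})

test_that("period-resolved matrices select by calendar year", {
  jem <- continuous_jem(data.frame(
    occupation = c("11", "11"), period_start = c(1950, 1990),
    period_end = c(1989, 2020), probability = c(80, 20),
    intensity = c(5, 1), frequency = c(50, 10)))
  expect_equal(jem_lookup(jem, "11", period = 1960)$probability, 80)
  expect_equal(jem_lookup(jem, "11", period = 2000)$probability, 20)
  expect_error(jem_lookup(jem, "11"), "period")
})

test_that("total exposure is the product of proportion-scaled indices", {
  expect_equal(total_exposure(data.frame(probability = 100, intensity = 1,
                                         frequency = 100)), 1)
  expect_equal(total_exposure(data.frame(probability = 50, intensity = 2,
                                         frequency = 50)), 0.5)
  expect_equal(total_exposure(data.frame(probability = 0, intensity = 9,
                                         frequency = 90)), 0)
  expect_equal(total_exposure(jem_lookup(toy_cjem(), "22")),
               0.25 * 4 * 0.10)
})

test_that("dichotomize is exposed iff strictly positive", {
  expect_equal(dichotomize(c(0, 1e-9, 0.5)),
               c("not_exposed", "exposed", "exposed"))
  expect_error(dichotomize(-1), "non-negative")
})

test_that("gold_exposed matches brute-force selection", {
  jem <- toy_cjem()
  occ <- c("11", "12", "21", "22", "99")
  expect_equal(gold_exposed(jem, occ), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  ojem <- toy_ojem()
  expect_equal(gold_exposed(ojem, occ), c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # all-zero JEM: empty subset; all-positive: full set
  zero <- generate_continuous_jem(c("1", "2"), exposed_fraction = 0, seed = 1)
  expect_false(any(gold_exposed(zero, c("1", "2"))))
  full <- generate_continuous_jem(c("1", "2"), exposed_fraction = 1, seed = 1)
  expect_true(all(gold_exposed(full, c("1", "2"))))
})

test_that("continuous evaluation: perfect prediction maxes every metric", {
  jem <- toy_cjem()
  occ <- c("11", "12", "21", "22", "11", "12")
  ev <- evaluate_continuous(occ, occ, jem)
  expect_equal(ev$all$accuracy, 100)
  expect_equal(ev$all$kappa, 1)
  expect_equal(ev$all$dichotomous_accuracy, 100)
  expect_equal(ev$all$kendall_tau, 1)
  expect_equal(ev$n_exposed, 4L)  # "12" carries zero exposure
  expect_equal(ev$exposed$accuracy, 100)
})

test_that("continuous evaluation metrics against hand computation", {
  jem <- toy_cjem()
  gold <- c("11", "12", "21", "22")
  pred <- c("11", "21", "12", "22")   # two swapped
  ev <- evaluate_continuous(gold, pred, jem)
  tg <- total_exposure(jem_lookup(jem, gold))
  tp <- total_exposure(jem_lookup(jem, pred))
  expect_equal(ev$all$accuracy, 100 * mean(tg == tp))
  expect_equal(ev$all$kappa, cohens_kappa(as.character(tp), as.character(tg)))
  expect_equal(ev$all$dichotomous_accuracy,
               100 * mean(dichotomize(tp) == dichotomize(tg)))
  expect_gte(ev$all$dichotomous_accuracy, ev$all$accuracy)  # coarsening
  expect_equal(ev$all$kendall_tau, oracle_tau(tg, tp), tolerance = 1e-12)
  # exposed subset = gold-exposed rows only
  expect_equal(ev$n_exposed, sum(tg > 0))
})

test_that("pair-keyed matrices use both codes and the min confidence", {
  jem <- continuous_jem(data.frame(
    occupation = c("11", "11", "22"), sector = c("A", "B", "A"),
    probability = c(100, 0, 50), intensity = c(1, 0, 2),
    frequency = c(100, 0, 50)))
  gold <- data.frame(occupation = c("11", "11", "22"),
                     sector = c("A", "B", "A"))
  pred <- data.frame(occupation = c("11", "11", "22"),
                     sector = c("B", "B", "A"))
  ev <- evaluate_continuous(gold, pred, jem,
                            confidences = cbind(c(0.99, 0.98, 0.97),
                                                c(0.10, 0.97, 0.96)))
  expect_equal(ev$all$accuracy, 100 * 2 / 3)
  # min confidence puts the first record in the lowest bins
  expect_equal(ev$all$bins$count[3], 1L)   # 0.10 -> [10,15)
  expect_equal(sum(ev$all$bins$count), 3L)
  expect_error(evaluate_continuous("11", "11", jem), "sector")
})

test_that("ordinal evaluation: one wrong agent fails the episode", {
  jem <- toy_ojem()
  gold <- c("12", "21", "22", "11")
  pred <- c("12", "22", "22", "11")   # one swap: episode 2 wrong
  ev <- evaluate_ordinal(gold, pred, jem)
  expect_equal(ev$all$accuracy, 75)
  pa <- ev$all$per_agent
  expect_equal(pa$accuracy[pa$agent == "dust"], 75)
  expect_equal(pa$accuracy[pa$agent == "fumes"], 75)
  expect_equal(pa$accuracy[pa$agent == "solvents"], 100)
  # conjunction bound: overall <= min per-agent accuracy
  expect_lte(ev$all$accuracy, min(pa$accuracy))
  # per-level accuracy: dust gold levels for episodes 1..4 are 1,2,0,0
  pl <- ev$all$per_level
  dust0 <- pl[pl$agent == "dust" & pl$level == 0, ]
  expect_equal(dust0$n, 2L)
  expect_equal(dust0$accuracy, 100)
  dust2 <- pl[pl$agent == "dust" & pl$level == 2, ]
  expect_equal(dust2$accuracy, 0)     # episode 2: gold 2, pred 0
  # exposed subset drops the all-zero gold episode
  expect_equal(ev$n_exposed, 3L)
  expect_equal(ev$exposed$accuracy, 100 * 2 / 3)
  # perfect prediction maxes everything
  ev2 <- evaluate_ordinal(gold, gold, jem)
  expect_equal(ev2$all$accuracy, 100)
  expect_equal(min(ev2$all$per_agent$kappa), 1)
})

test_that("kendall_tau is tie-corrected and errors on constant input", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  expect_error(kendall_tau(1, 1), "length")
  set.seed(8)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    x <- sample(0:3, n, replace = TRUE)   # heavy ties, like exposure totals
    y <- x + sample(-1:1, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, oracle_tau(x, y), tolerance = 1e-12)
  }
})

test_that("jem constructors validate ranges and keys", {
  expect_error(continuous_jem(data.frame(occupation = "1", probability = 120,
                                         intensity = 1, frequency = 10)),
               "\\[0, 100\\]")
  expect_error(continuous_jem(data.frame(occupation = c("1", "1"),
                                         probability = 1, intensity = 1,
                                         frequency = 1)), "duplicate")
  expect_error(ordinal_jem(data.frame(occupation = "1", dust = 3L)),
               "outside 0..2")
})
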