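test_that("filter_viable rejects uncoded, invalid and incomplete records", {
  sc <- builtin_scheme("isco88")
  rec <- data.frame(entry_id = sprintf("e%d", 1:10),
                    occupation = letters[1:10],
                    gold = c("2221", "2222", "121#", NA, "3111", "12##",
                             "9999", "bad!", "2221", ""))
  fv <- filter_viable(rec, sc, quiet = TRUE)
  expect_equal(nrow(fv$viable), 5L)
  expect_equal(sort(unique(fv$rejected$reason)),
               c("incomplete", "invalid", "uncoded"))
  expect_equal(sum(fv$rejected$reason == "uncoded"), 2L)

  all_ok <- data.frame(entry_id = "a", gold = "2221")
  expect_equal(nrow(filter_viable(all_ok, sc, quiet = TRUE)$rejected), 0L)
  expect_error(filter_viable(data.frame(entry_id = "a"), sc, quiet = TRUE),
               "no `gold` column")
})

test_that("split_dataset uses largest-remainder sizes and is seed-stable", {
  rec <- data.frame(entry_id = sprintf("e%d", 1:100), x = 1:100)
  sp <- split_dataset(rec, seed = 7)
  expect_equal(c(nrow(sp$train), nrow(sp$test), nrow(sp$validation)),
               c(60L, 30L, 10L))
  expect_equal(sort(c(sp$train$entry_id, sp$test$entry_id,
                      sp$validation$entry_id)), sort(rec$entry_id))
  sp2 <- split_dataset(rec, seed = 7)
  expect_identical(sp$train$entry_id, sp2$train$entry_id)
  sp3 <- split_dataset(rec, seed = 8)
  expect_false(identical(sp$train$entry_id, sp3$train$entry_id))
  # non-divisible sizes still exhaustive and disjoint
  rec2 <- rec[1:7, ]
  sp4 <- split_dataset(rec2, seed = 1)
  expect_equal(nrow(sp4$train) + nrow(sp4$test) + nrow(sp4$validation), 7L)
  expect_error(split_dataset(rec[1:2, ], seed = 1), "degenerate split")
  expect_error(split_dataset(rec, fractions = c(0.5, 0.6), seed = 1),
               "sum to 1")
})

test_that("augment_with_index adds classes, flags origin, dedupes", {
  sc <- toy_scheme()
  train <- data.frame(entry_id = c("a", "b"), occupation = c("x1", "y2"),
                      gold = c("11", "22"))
  index <- data.frame(occupation = c("x1", "y2", "z3", "z3", "w4"),
                      gold = c("11", "22", "33", "33", "44"))
  out <- augment_with_index(train, index, sc)
  expect_equal(sum(out$.origin == "index"), 4L)  # one duplicate dropped
  expect_equal(length(unique(out$gold)), 4L)
  expect_identical(augment_with_index(train, index[0, ], sc)$gold, train$gold)
  expect_error(augment_with_index(train, data.frame(occupation = "q",
                                                    gold = "9#"), sc),
               "complete")
})

test_that("trained coder recovers the clean corpus and is deterministic", {
  fx <- recovery_fixture()
  expect_gte(accuracy(fx$top$code, fx$gold), 99)
  # label table covers exactly the training codes (index makes it all codes)
  expect_setequal(fx$coder$labels, fx$codes)
  # same seed => identical predictions
  coder2 <- train_coder(fx$split, fx$scheme, fx$embedder,
                        c("occupation", "sector"))
  sugg2 <- predict_topk(coder2, fx$split$test, k = 5)
  expect_identical(fx$suggestions, sugg2)
  # two identical records get identical suggestion lists
  one <- fx$split$test[c(1, 1), ]
  one$entry_id <- c("p", "q")
  s <- predict_topk(fx$coder, one, k = 3)
  expect_equal(s$code[s$entry_id == "p"], s$code[s$entry_id == "q"])
  expect_equal(s$confidence[s$entry_id == "p"],
               s$confidence[s$entry_id == "q"])
})

test_that("predict_topk confidences are ranked, normalized probabilities", {
  fx <- recovery_fixture()
  k_all <- length(fx$coder$labels)
  s <- predict_topk(fx$coder, fx$split$test[1:5, ], k = k_all)
  for (id in unique(s$entry_id)) {
    si <- s[s$entry_id == id, ]
    expect_true(all(diff(si$confidence) <= 1e-12))   # non-increasing in rank
    expect_equal(sum(si$confidence), 1, tolerance = 1e-6)
  }
  # k above the class count returns all classes
  s2 <- predict_topk(fx$coder, fx$split$test[1, ], k = 10 * k_all)
  expect_equal(nrow(s2), k_all)
})

test_that("train_coder validates inputs", {
  sc <- toy_scheme()
  rec <- data.frame(entry_id = sprintf("e%d", 1:20),
                    occupation = rep(c("aa1", "bb2"), 10),
                    gold = rep(c("11", "22"), 10))
  emb <- hash_embedder(dim = 16, language = "none")
  sp <- split_dataset(rec, seed = 1)
  one_class <- sp
  one_class$train$gold <- "11"
  expect_error(train_coder(one_class, sc, emb, "occupation"),
               "degenerate model")
  no_val <- sp
  no_val$validation <- no_val$validation[0, ]
  expect_error(train_coder(no_val, sc, emb, "occupation"), "validation")
})

test_that("save/load round trip reproduces suggestions bitwise", {
  fx <- recovery_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_coder(fx$coder, path)
  back <- load_coder(path)
  expect_identical(predict_topk(back, fx$split$test, k = 5), fx$suggestions)
  expect_equal(back$labels, fx$coder$labels)
})

test_that("wrapper selection never picks pure noise over signal", {
  sc <- toy_scheme()
  set.seed(5)
  n <- 240
  gold <- sample(c("11", "12", "21", "22"), n, replace = TRUE)
  rec <- data.frame(
    entry_id = sprintf("e%d", 1:n),
    informative = paste0("sig", gold),
    noise = sprintf("rnd%d", sample(1:30, n, replace = TRUE)),
    gold = gold)
  sp <- split_dataset(rec, seed = 3)
  emb <- hash_embedder(dim = 64, language = "none")
  sel <- select_input_classes(sp, sc, emb, c("informative", "noise"),
                              coder_params(nrounds = 60))
  expect_equal(nrow(sel$scores), 3L)  # 2^2 - 1 subsets
  expect_true("informative" %in% sel$best)
  acc_tab <- setNames(sel$scores$accuracy, sel$scores$classes)
  expect_gt(acc_tab[["informative"]], acc_tab[["noise"]])
  # single candidate trivially selected
  sel1 <- select_input_classes(sp, sc, emb, "informative",
                               coder_params(nrounds = 60))
  expect_equal(sel1$best, "informative")
  expect_error(select_input_classes(sp, sc, emb, letters[1:7]), "1-6")
})

test_that("per-level accuracy is monotone for the trained coder", {
  fx <- recovery_fixture()
  lvl <- per_level_metrics(fx$top$code, fx$gold, fx$scheme)
  expect_true(all(diff(lvl$accuracy) <= 0))
})
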