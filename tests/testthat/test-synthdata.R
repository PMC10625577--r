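test_that("generate_scheme hits the requested outcome-category counts", {
  gen <- generate_scheme(c(5, 25, 100))
  expect_equal(length(gen$codes), 100L)
  codes <- parse_code(gen$scheme, gen$codes)
  expect_equal(count_outcome_categories(codes, 1), 5L)
  expect_equal(count_outcome_categories(codes, 2), 25L)
  expect_equal(count_outcome_categories(codes, 3), 100L)
  # degenerate chain
  chain <- generate_scheme(c(2, 2, 2))
  expect_equal(length(chain$codes), 2L)
  expect_error(generate_scheme(c(10, 5)), "non-decreasing")
})

test_that("generate_corpus is reproducible and honours its knobs", {
  gen <- generate_scheme(c(4, 12))
  sp <- corpus_spec(gen$scheme, gen$codes, n_entries = 600, noise_rate = 0.2,
                    imbalance = 1, incomplete_rate = 0.1, seed = 3)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$records), 600L)
  # index: one clean description per code, complete codes
  expect_equal(nrow(c1$index), 12L)
  expect_setequal(c1$index$gold, gen$codes)
  # incomplete fraction near the target
  inc <- grepl("#", c1$records$gold, fixed = TRUE)
  expect_gt(mean(inc), 0.05)
  expect_lt(mean(inc), 0.2)
  # power-law imbalance: largest class much bigger than smallest
  sizes <- table(c1$records$gold[!inc])
  expect_gt(max(sizes) / min(sizes), 5)
  # balanced spec gives near-equal classes
  bal <- generate_corpus(corpus_spec(gen$scheme, gen$codes, n_entries = 600,
                                     imbalance = 0, incomplete_rate = 0,
                                     seed = 3))
  bs <- table(bal$records$gold)
  expect_lte(max(bs) - min(bs), 1)
})

test_that("words-per-class median lands near the target", {
  gen <- generate_scheme(c(4, 12))
  sp <- corpus_spec(gen$scheme, gen$codes, n_entries = 5000,
                    words_median = 2, incomplete_rate = 0, seed = 5)
  corpus <- generate_corpus(sp)
  wc <- lengths(strsplit(corpus$records$occupation, " "))
  expect_lte(abs(median(wc) - 2), 1)
  expect_gte(min(wc), 1)
})

test_that("synthetic tokens are stemming-invariant", {
  gen <- generate_scheme(c(4, 12))
  corpus <- generate_corpus(corpus_spec(gen$scheme, gen$codes,
                                        n_entries = 100, seed = 1))
  toks <- unique(unlist(strsplit(corpus$records$occupation, " ")))
  expect_identical(stem_tokens(toks), toks)
})

test_that("continuous JEM generator respects the exposed fraction", {
  codes <- sprintf("c%03d", 1:1000)
  jem <- generate_continuous_jem(codes, exposed_fraction = 0.1, seed = 2)
  totals <- total_exposure(jem_lookup(jem, codes))
  k <- sum(totals > 0)
  # within the binomial 99% CI of n=1000, p=0.1
  expect_gt(k, 1000 * 0.1 - 2.58 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(k, 1000 * 0.1 + 2.58 * sqrt(1000 * 0.1 * 0.9))
  none <- generate_continuous_jem(codes[1:50], exposed_fraction = 0, seed = 2)
  expect_true(all(total_exposure(jem_lookup(none, codes[1:50])) == 0))
  all_exp <- generate_continuous_jem(codes[1:50], exposed_fraction = 1, seed = 2)
  expect_true(all(total_exposure(jem_lookup(all_exp, codes[1:50])) > 0))
})

test_that("ordinal JEM generator covers every agent with levels 0-2", {
  codes <- sprintf("c%02d", 1:80)
  jem <- generate_ordinal_jem(codes, agents = 12, exposed_fraction = 0.3,
                              seed = 4)
  expect_equal(length(jem$agents), 12L)
  lv <- as.matrix(jem_lookup(jem, codes))
  expect_equal(dim(lv), c(80L, 12L))
  expect_true(all(lv %in% 0:2))
  # exposed codes have at least one non-zero agent; reproducible
  expect_identical(jem$entries,
                   generate_ordinal_jem(codes, agents = 12,
                                        exposed_fraction = 0.3,
                                        seed = 4)$entries)
  expect_error(generate_ordinal_jem(codes, agents = character(0)),
               "non-empty")
})

test_that("noise monotonically degrades accuracy (3 seeds per level)", {
  gen <- generate_scheme(c(4, 12))
  emb <- hash_embedder(dim = 128, language = "none")
  mean_acc <- vapply(c(0, 0.45), function(nr) {
    mean(vapply(1:3, function(sd) {
      sp <- corpus_spec(gen$scheme, gen$codes, n_entries = 360,
                        noise_rate = nr, imbalance = 0, incomplete_rate = 0,
                        vocab_per_code = 2, seed = sd)
      corpus <- generate_corpus(sp)
      spl <- split_dataset(corpus$records, seed = 42)
      coder <- train_coder(spl, gen$scheme, emb, c("occupation", "sector"))
      sugg <- predict_topk(coder, spl$test, k = 1)
      accuracy(sugg$code,
               code_canonical(parse_code(gen$scheme, spl$test$gold)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_acc[1], mean_acc[2])
})
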