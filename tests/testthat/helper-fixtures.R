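# Shared fixtures and independent oracles.  The recovery fixture trains one
# coder on the canonical clean world and is cached across test files.

.fixture_env <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(.fixture_env$rec)) return(.fixture_env$rec)
  rw <- recovery_corpus_spec()  # 20 codes x 50 examples, noise 0, seed 1
  corpus <- generate_corpus(rw$spec)
  split <- split_dataset(corpus$records, seed = 42)
  split$train <- augment_with_index(split$train, corpus$index, rw$scheme)
  emb <- hash_embedder(dim = 256, language = "none")
  coder <- train_coder(split, rw$scheme, emb, c("occupation", "sector"))
  sugg <- predict_topk(coder, split$test, k = 5)
  .fixture_env$rec <- list(
    scheme = rw$scheme, codes = rw$codes, corpus = corpus, split = split,
    embedder = emb, coder = coder, suggestions = sugg,
    top = sugg[sugg$rank == 1L, ],
    gold = code_canonical(parse_code(rw$scheme, split$test$gold)))
  .fixture_env$rec
}

# brute-force Cohen's kappa: explicit Po / Pe from definition, no marginals
# shared with the implementation
oracle_kappa <- function(a, b) {
  n <- length(a)
  po <- 0
  for (i in seq_len(n)) po <- po + (a[i] == b[i])
  po <- po / n
  pe <- 0
  for (lab in unique(c(a, b))) {
    pa <- sum(a == lab) / n
    pb <- sum(b == lab) / n
    pe <- pe + pa * pb
  }
  if (pe >= 1 - 1e-15) return(1)
  (po - pe) / (1 - pe)
}

# O(n^2) pair-count Kendall tau-b
oracle_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# small two-level scheme for cheap unit tests
toy_scheme <- function() {
  scheme_spec("TOY", levels = list(1, 2), alphabet = "0123456789")
}
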