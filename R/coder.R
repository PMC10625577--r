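#' Hyperparameters for the boosted-tree coder
#'
#' Defaults are the pre-defined setting empirically derived for large
#' free-text occupational corpora and used unchanged for every
#' classification model here: early stopping after 1 round without
#' validation-loss improvement, eta 0.6, max_delta_step 1, max_depth 20,
#' gamma 1.5, lambda 1e-4, min_child_weight 0, subsample 0.75,
#' colsample_bytree 1, colsample_bylevel 1. `nrounds` caps boosting
#' rounds (the stopping rule, not the cap, is what normally ends
#' training); `seed` drives row/column subsampling.
#'
#' @param eta learning rate.
#' @param max_delta_step cap on the absolute leaf weight (0 disables).
#' @param max_depth maximum tree depth.
#' @param gamma minimum loss reduction required to split.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum hessian sum per child.
#' @param subsample row subsampling rate per tree.
#' @param colsample_bytree,colsample_bylevel column subsampling rates.
#' @param early_stopping_rounds rounds without validation improvement
#'   before stopping.
#' @param nrounds maximum boosting rounds.
#' @param seed integer RNG seed for subsampling.
#' @return a list of class `coder_params`.
#' @export
coder_params <- function(eta = 0.6, max_delta_step = 1, max_depth = 20L,
                         gamma = 1.5, lambda = 1e-4, min_child_weight = 0,
                         subsample = 0.75, colsample_bytree = 1,
                         colsample_bylevel = 1, early_stopping_rounds = 1L,
                         nrounds = 500L, seed = 42L) {
  p <- list(eta = eta, max_delta_step = max_delta_step,
            max_depth = as.integer(max_depth), gamma = gamma,
            lambda = lambda, min_child_weight = min_child_weight,
            subsample = subsample, colsample_bytree = colsample_bytree,
            colsample_bylevel = colsample_bylevel,
            early_stopping_rounds = as.integer(early_stopping_rounds),
            nrounds = as.integer(nrounds), seed = as.integer(seed))
  stopifnot(p$eta > 0, p$max_depth >= 1, p$subsample > 0, p$subsample <= 1,
            p$nrounds >= 1)
  class(p) <- "coder_params"
  p
}

#' Split off training-viable records
#'
#' An episode is viable for model training only if its gold-standard code
#' is complete: the system must be able to suggest complete codes, so
#' placeholder-bearing codes are rejected. Records without a gold code are
#' rejected with reason `"uncoded"`, unparseable codes with `"invalid"`,
#' placeholder-bearing ones with `"incomplete"`.
#'
#' @param records data frame with a `gold` column of code strings.
#' @param scheme the [scheme_spec()] the gold codes belong to.
#' @param quiet suppress the count message.
#' @return list with `viable` and `rejected` data frames (`rejected`
#'   carries a `reason` column).
#' @export
filter_viable <- function(records, scheme, quiet = FALSE) {
  stopifnot(is.data.frame(records))
  if (!"gold" %in% names(records)) {
    stop_data("records carry no `gold` column")
  }
  gold <- as.character(records$gold)
  reason <- rep(NA_character_, nrow(records))
  uncoded <- is.na(gold) | !nzchar(trimws(gold))
  reason[uncoded] <- "uncoded"
  idx <- which(!uncoded)
  for (i in idx) {
    parsed <- tryCatch(parse_code(scheme, gold[i]), error = function(e) NULL)
    if (is.null(parsed)) {
      reason[i] <- "invalid"
    } else if (!is_complete(parsed)) {
      reason[i] <- "incomplete"
    }
  }
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  if (!quiet) {
    message(sprintf("filter_viable: %d viable, %d rejected (%s)",
                    sum(keep), sum(!keep),
                    paste(sprintf("%s: %d", names(table(rejected$reason)),
                                  table(rejected$reason)), collapse = ", ")))
  }
  list(viable = records[keep, , drop = FALSE], rejected = rejected)
}

#' Randomly partition records into train / test / validation sets
#'
#' Sizes follow largest-remainder rounding of the fractions (so 100
#' records at 0.6/0.3/0.1 give exactly 60/30/10); the same seed always
#' reproduces the same partition.
#'
#' @param records data frame.
#' @param fractions positive fractions summing to 1, named
#'   train/test/validation.
#' @param seed integer seed.
#' @return list of class `dataset_split` with `train`, `test`,
#'   `validation` data frames plus the fractions and seed used.
#' @export
split_dataset <- function(records,
                          fractions = c(train = 0.6, test = 0.3,
                                        validation = 0.1),
                          seed = 42L) {
  stopifnot(is.data.frame(records))
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_data("fractions must be positive and sum to 1")
  }
  n <- nrow(records)
  k <- length(fractions)
  if (n < k) stop_data("degenerate split: ", n, " records for ", k, " parts")
  base <- floor(n * fractions)
  rem <- n * fractions - base
  left <- n - sum(base)
  if (left > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[bump] <- base[bump] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(base)
  starts <- c(1L, head(ends, -1L) + 1L)
  parts <- lapply(seq_len(k), function(i) {
    records[sort(perm[starts[i]:ends[i]]), , drop = FALSE]
  })
  names(parts) <- names(fractions) %||% c("train", "test", "validation")[seq_len(k)]
  structure(c(parts, list(fractions = fractions, seed = as.integer(seed))),
            class = "dataset_split")
}

#' Supplement training data with coding-index descriptions
#'
#' The coding index holds one canonical description per code; adding it to
#' the training set makes every code of the classification a trainable
#' class even when the cohort never used it. Index entries must carry
#' complete codes; duplicates (same code and texts) are dropped.
#'
#' @param train training-partition data frame.
#' @param index data frame of index entries with a `gold` column and the
#'   same input-class columns.
#' @param scheme the [scheme_spec()] the codes belong to.
#' @return the concatenated data frame; a `.origin` column distinguishes
#'   `"data"` from `"index"` rows.
#' @export
augment_with_index <- function(train, index, scheme) {
  stopifnot(is.data.frame(train))
  train$.origin <- train$.origin %||% rep("data", nrow(train))
  if (is.null(index) || nrow(index) == 0L) return(train)
  parsed <- parse_code(scheme, index$gold)  # invalid codes error here
  if (!all(is_complete(parsed))) {
    stop_data("coding-index entries must carry complete codes")
  }
  text_cols <- setdiff(names(index), c("entry_id", ".origin"))
  key <- do.call(paste, c(index[text_cols], sep = "\r"))
  index <- index[!duplicated(key), , drop = FALSE]
  index$.origin <- "index"
  if (is.null(index$entry_id)) {
    index$entry_id <- sprintf("idx_%d", seq_len(nrow(index)))
  }
  common <- union(names(train), names(index))
  for (cn in setdiff(common, names(train))) train[[cn]] <- ""
  for (cn in setdiff(common, names(index))) index[[cn]] <- ""
  rbind(train[common], index[common])
}

#' Train the gradient-boosted-tree occupational coder
#'
#' Trains one multiclass boosted-tree ensemble per classification on the
#' training partition only; the validation partition is used exclusively
#' for early stopping (monitored metric: multiclass log-loss). Class
#' imbalance is deliberately left untouched: synthetic re-balancing is not
#' applicable to corpora whose minority classes hold a single example.
#'
#' @param split a [split_dataset()] result whose `train` part may have
#'   been extended via [augment_with_index()].
#' @param scheme the [scheme_spec()] of the gold codes.
#' @param embedder an [hash_embedder()] or [custom_embedder()].
#' @param input_classes character vector of input-class columns to use.
#' @param params a [coder_params()].
#' @return an object of class `occ_coder`.
#' @export
train_coder <- function(split, scheme, embedder, input_classes,
                        params = coder_params()) {
  stopifnot(inherits(split, "dataset_split"), inherits(params, "coder_params"))
  train <- split$train
  val <- split$validation
  if (is.null(val) || nrow(val) == 0L) {
    stop_data("validation set is empty; early stopping needs one")
  }
  gold_codes <- parse_code(scheme, train$gold)
  if (!all(is_complete(gold_codes))) {
    stop_data("training gold codes must be complete; run filter_viable()")
  }
  labels <- sort(unique(code_canonical(gold_codes)))
  if (length(labels) < 2L) {
    stop_data("degenerate model: fewer than 2 distinct gold codes")
  }
  y <- match(code_canonical(gold_codes), labels) - 1L
  X <- build_feature_matrix(train, embedder, input_classes)$matrix

  val_codes <- code_canonical(parse_code(scheme, val$gold))
  yv <- match(val_codes, labels) - 1L
  vkeep <- !is.na(yv)  # validation codes unseen in training can't be scored
  Xv <- build_feature_matrix(val, embedder, input_classes)$matrix
  if (!any(vkeep)) {
    stop_data("no validation record carries a trainable code")
  }
  fit <- .gbt_train(X, y, length(labels),
                    Xv[vkeep, , drop = FALSE], yv[vkeep],
                    params[c("eta", "gamma", "lambda", "min_child_weight",
                             "subsample", "colsample_bytree",
                             "colsample_bylevel", "max_delta_step",
                             "max_depth")],
                    params$nrounds, params$early_stopping_rounds,
                    params$seed)
  structure(list(model = fit, scheme = scheme, labels = labels,
                 embedder_id = embedder$identifier,
                 embedder_spec = embedder$spec,
                 input_classes = input_classes, params = unclass(params),
                 metadata = list(rounds = fit$best_round,
                                 monitored = "validation multiclass log-loss",
                                 n_train = nrow(train),
                                 seed = params$seed)),
            class = "occ_coder")
}

#' @export
print.occ_coder <- function(x, ...) {
  cat(sprintf(paste0("<occ_coder> scheme %s: %d classes, %d boosting ",
                     "round(s), embedder %s, input classes: %s\n"),
              x$scheme$name, length(x$labels), x$metadata$rounds,
              x$embedder_id, paste(x$input_classes, collapse = ", ")))
  invisible(x)
}

#' Suggest the top-k codes for new records
#'
#' Returns the k highest-probability complete codes per record with their
#' confidence scores (softmax class probabilities). Ties are broken by
#' label-table order; over all classes the confidences sum to 1.
#'
#' @param coder an [train_coder()] result.
#' @param records data frame of records (needs the coder's input-class
#'   columns and, ideally, `entry_id`).
#' @param k number of suggestions per record (capped at the class count).
#' @param embedder optional embedder override (required if the coder was
#'   trained with a [custom_embedder()] and then reloaded).
#' @return data frame with columns `entry_id`, `rank`, `code`,
#'   `confidence`.
#' @export
predict_topk <- function(coder, records, k = 10L, embedder = NULL) {
  stopifnot(inherits(coder, "occ_coder"), k >= 1L)
  if (is.null(embedder)) embedder <- embedder_from_spec(coder$embedder_spec)
  fm <- build_feature_matrix(records, embedder, coder$input_classes)
  P <- .gbt_predict(coder$model, fm$matrix)
  k <- min(as.integer(k), length(coder$labels))
  out <- lapply(seq_len(nrow(P)), function(i) {
    ord <- order(-P[i, ], seq_along(coder$labels))[seq_len(k)]
    data.frame(entry_id = fm$entry_id[i], rank = seq_len(k),
               code = coder$labels[ord], confidence = P[i, ord])
  })
  do.call(rbind, out)
}

#' Exhaustive wrapper selection of input classes
#'
#' Trains one coder per non-empty subset of the candidate input classes on
#' the same split and scores each on test-set accuracy. Ties go to the
#' smaller subset, then lexicographic order. Refuses more than 6
#' candidates (2^n - 1 models).
#'
#' @param split a [split_dataset()] result.
#' @param scheme,embedder,params as in [train_coder()].
#' @param candidate_classes character vector of 1-6 input-class names.
#' @return list with `best` (character vector) and `scores` (data frame
#'   with one row per subset: `classes`, `n_classes`, `accuracy`).
#' @export
select_input_classes <- function(split, scheme, embedder, candidate_classes,
                                 params = coder_params()) {
  n <- length(candidate_classes)
  if (n < 1L || n > 6L) {
    stop_data("1-6 candidate classes supported (got ", n, "); an exhaustive ",
              "wrapper over more would train over 64 models - prune first")
  }
  subsets <- unlist(lapply(seq_len(n), function(sz) {
    lapply(asplit(utils::combn(sort(candidate_classes), sz), 2), as.character)
  }), recursive = FALSE)
  gold <- code_canonical(parse_code(scheme, split$test$gold))
  scores <- vapply(subsets, function(cls) {
    coder <- train_coder(split, scheme, embedder, cls, params)
    sugg <- predict_topk(coder, split$test, k = 1L, embedder = embedder)
    accuracy(sugg$code, gold)
  }, numeric(1))
  tab <- data.frame(
    classes = vapply(subsets, paste, character(1), collapse = "+"),
    n_classes = vapply(subsets, length, integer(1)),
    accuracy = scores)
  best <- order(-tab$accuracy, tab$n_classes, tab$classes)[1]
  list(best = subsets[[best]], scores = tab)
}

#' Save a trained coder to a single-file JSON bundle
#'
#' The bundle holds the boosted trees, label table, scheme definition,
#' embedder descriptor, hyperparameters and a configuration hash; loading
#' it reproduces bitwise-identical suggestion lists. Coders trained with a
#' [custom_embedder()] store only the embedder identifier and need the
#' embedder re-supplied at prediction time.
#'
#' @param coder an `occ_coder`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_coder <- function(coder, path) {
  stopifnot(inherits(coder, "occ_coder"))
  model <- coder$model
  # doubles are stored as 17-significant-digit strings: JSON writers round
  # otherwise, and the save/load contract is bitwise-identical predictions
  model$rounds <- lapply(model$rounds, function(kt) {
    lapply(kt, function(t) {
      t$thr <- sprintf("%.17g", t$thr)
      t$leaf <- sprintf("%.17g", t$leaf)
      t
    })
  })
  bundle <- list(
    format = "occ_coder/1",
    model = model,
    labels = coder$labels,
    scheme = scheme_to_list(coder$scheme),
    embedder_id = coder$embedder_id,
    embedder_spec = coder$embedder_spec,
    input_classes = coder$input_classes,
    params = coder$params,
    metadata = coder$metadata)
  bundle$hash <- config_hash(bundle[c("labels", "embedder_id",
                                      "input_classes", "params")])
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a coder bundle written by [save_coder()]
#' @param path bundle path.
#' @return an `occ_coder`.
#' @export
load_coder <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(b$format, "occ_coder/1")) {
    stop_data("not a coder bundle: ", path)
  }
  model <- b$model
  model$rounds <- lapply(model$rounds, function(kt) {
    lapply(kt, function(t) {
      list(feat = as.integer(t$feat), thr = as.numeric(t$thr),
           leaf = as.numeric(t$leaf), left = as.integer(t$left),
           right = as.integer(t$right))
    })
  })
  model$nclass <- as.integer(model$nclass)
  model$nfeat <- as.integer(model$nfeat)
  structure(list(model = model, scheme = scheme_from_list(b$scheme),
                 labels = as.character(b$labels),
                 embedder_id = b$embedder_id,
                 embedder_spec = b$embedder_spec,
                 input_classes = as.character(b$input_classes),
                 params = b$params, metadata = b$metadata),
            class = "occ_coder")
}

scheme_to_list <- function(scheme) {
  list(name = scheme$name,
       levels = lapply(scheme$levels, function(l) {
         if (is.character(l)) list(lookup = as.list(l)) else as.integer(l)
       }),
       separators = if (nrow(scheme$separators)) {
         paste0(scheme$separators$pos, ":", scheme$separators$char)
       } else {
         character(0)
       },
       placeholder = scheme$placeholder,
       alphabet = scheme$alphabet)
}

scheme_from_list <- function(l) {
  levels <- lapply(l$levels, function(lv) {
    if (is.list(lv) && !is.null(lv$lookup)) {
      return(unlist(lv$lookup))
    }
    as.integer(lv)
  })
  scheme_spec(name = l$name, levels = levels,
              separators = as.character(unlist(l$separators) %||% character(0)),
              placeholder = l$placeholder,
              alphabet = if (is.null(l$alphabet)) NULL else as.character(unlist(l$alphabet)))
}
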