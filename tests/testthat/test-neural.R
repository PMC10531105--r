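test_that("tokenizer vocabulary is deterministic, capped, with reserved ids", {
  texts <- shared_corpus()$conclusion_text[1:40]
  a <- build_tokenizer(texts)
  b <- build_tokenizer(texts)
  expect_identical(a$vocab, b$vocab)
  capped <- build_tokenizer(texts, vocab_cap = 100)
  expect_lte(length(capped$vocab), 100 + 4)
  expect_identical(encode_ids(a, "zzzunseenzzz"), radresponse:::UNK_ID)
  expect_error(build_tokenizer(character(0)), "empty")
})

test_that("analytic gradients match finite differences for every architecture", {
  specs <- list(
    encoder_spec("tiny_transformer", embedding_dim = 8L, n_layers = 2L,
                 n_heads = 2L, ff_dim = 12L, max_seq_len = 10L),
    encoder_spec("bilstm", embedding_dim = 6L, hidden_size = 5L,
                 dense_units = 7L, max_seq_len = 10L),
    encoder_spec("cnn", embedding_dim = 6L, kernel_size = 3L, n_filters = 5L,
                 dense_units = 7L, max_seq_len = 10L)
  )
  ids <- c(5L, 6L, 7L, 5L, 8L)
  y <- 2L
  eps <- 1e-5
  setel <- function(tree, path, ii, val) {
    if (!length(path)) { tree[ii] <- val; return(tree) }
    tree[[path[1]]] <- setel(tree[[path[1]]], path[-1], ii, val)
    tree
  }
  leaf_paths <- function(tree, prefix = character(0)) {
    if (!is.list(tree)) return(list(prefix))
    out <- list()
    for (i in seq_along(tree)) {
      key <- if (!is.null(names(tree)) && nzchar(names(tree)[i])) names(tree)[i] else i
      out <- c(out, leaf_paths(tree[[i]], c(prefix, key)))
    }
    out
  }
  for (spec in specs) {
    set.seed(42)
    params <- radresponse:::init_classifier_params(spec, 12L)
    lossfn <- function(p) {
      -log(radresponse:::classifier_fwd(p, spec, ids)$p[y] + 1e-12)
    }
    fo <- radresponse:::classifier_fwd(params, spec, ids)
    onehot <- numeric(4); onehot[y] <- 1
    g <- radresponse:::classifier_bwd(params, spec, fo$cache, fo$p - onehot)
    for (path in leaf_paths(params)) {
      pl <- params; gl <- g
      for (k in path) { pl <- pl[[k]]; gl <- gl[[k]] }
      set.seed(7)
      for (ii in sample(length(pl), min(3, length(pl)))) {
        num <- (lossfn(setel(params, path, ii, pl[ii] + eps)) -
                lossfn(setel(params, path, ii, pl[ii] - eps))) / (2 * eps)
        expect_lt(abs(num - gl[ii]) / max(abs(num), abs(gl[ii]), 1e-3), 1e-3,
                  label = sprintf("%s %s[%d]", spec$kind,
                                  paste(path, collapse = "$"), ii))
      }
    }
  }
})

test_that("training rejects patient overlap between train and dev", {
  co <- separable_corpus(20)
  expect_error(train_supervised(co, co[1:5, ], tiny_tf_spec(),
                                train_config(epochs = 1)),
               "share patient")
})

test_that("consistency training with beta = 0 and no variant CE reduces to plain training", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:30, ]
  dv <- co[co$split == "dev", ][1:10, ]
  spec <- encoder_spec("cnn", embedding_dim = 8L, n_filters = 6L,
                       dense_units = 6L, max_seq_len = 32L)
  cfg <- train_config(epochs = 2, batch_size = 8)
  plain <- train_supervised(tr, dv, spec, cfg, seed = 4)
  red <- train_with_consistency(
    tr, dv, spec,
    aug = augmentation_config(P = 10, include_variants_in_ce = FALSE),
    w = consistency_weights(alpha = 1, beta = 0),
    config = cfg, seed = 4)
  expect_identical(plain$history, red$history)
  expect_identical(plain$params, red$params)
})

test_that("training is bit-reproducible given the seed", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:30, ]
  dv <- co[co$split == "dev", ][1:10, ]
  spec <- encoder_spec("bilstm", embedding_dim = 8L, hidden_size = 6L,
                       dense_units = 8L, max_seq_len = 32L)
  cfg <- train_config(epochs = 2, batch_size = 8)
  m1 <- train_supervised(tr, dv, spec, cfg, seed = 2)
  m2 <- train_supervised(tr, dv, spec, cfg, seed = 2)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("loss accounting holds at every logged step", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:25, ]
  dv <- co[co$split == "dev", ][1:10, ]
  m <- train_with_consistency(
    tr, dv, tiny_tf_spec(),
    aug = augmentation_config(P = 3),
    w = consistency_weights(alpha = 1, beta = 10),
    config = train_config(epochs = 3, batch_size = 8), seed = 1)
  expect_equal(m$history$total, 1 * m$history$ce + 10 * m$history$mse)
})

test_that("the transformer solves a separable fixture within 10 epochs", {
  tr <- separable_corpus(400)
  dv <- separable_corpus(60, offset = 1000)
  spec <- encoder_spec("tiny_transformer", embedding_dim = 16L, n_layers = 1L,
                       n_heads = 2L, ff_dim = 32L, max_seq_len = 16L)
  m <- train_supervised(tr, dv, spec,
                        train_config(epochs = 10, learning_rate = 3e-3), seed = 1)
  expect_gte(max(m$history$dev_accuracy), 0.95)
})

test_that("training loss trends downward over epochs", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:60, ]
  dv <- co[co$split == "dev", ][1:15, ]
  for (sd in 1:3) {
    m <- train_supervised(tr, dv, tiny_tf_spec(),
                          train_config(epochs = 5, learning_rate = 2e-3),
                          seed = sd)
    expect_lt(mean(tail(m$history$ce, 2)), mean(head(m$history$ce, 2)))
  }
})

test_that("predicted distributions are valid; ties break to the lowest code", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:30, ]
  dv <- co[co$split == "dev", ][1:10, ]
  m <- train_supervised(tr, dv, tiny_tf_spec(),
                        train_config(epochs = 1), seed = 1)
  P <- predict_proba(m, co[co$split == "test", ][1:10, ])
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(P >= 0))
  # symmetric toy weights: zero output layer forces a 4-way tie
  m$params$Wout[] <- 0
  m$params$bout[] <- 0
  expect_identical(unname(predict(m, "Stable disease.")), "NED")
  expect_error(predict_proba(m, "  "), "empty")
})

test_that("truncation is a no-op for short texts", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:30, ]
  dv <- co[co$split == "dev", ][1:10, ]
  spec_wide <- encoder_spec("cnn", embedding_dim = 8L, n_filters = 6L,
                            dense_units = 6L, max_seq_len = 200L)
  m <- train_supervised(tr, dv, spec_wide, train_config(epochs = 1), seed = 1)
  short <- "Stable liver lesion. No new lesion."
  ids_a <- encode_ids(m$tokenizer, short, 200)
  ids_b <- encode_ids(m$tokenizer, short, Inf)
  expect_identical(ids_a, ids_b)
})

test_that("the Bi-LSTM head has 64 then 4 units under the defaults", {
  spec <- encoder_spec("bilstm")
  params <- radresponse:::init_classifier_params(spec, 50L)
  expect_identical(dim(params$Wh1), c(64L, 64L))  # 2 x 32 concat -> 64 dense
  expect_identical(dim(params$Wout), c(64L, 4L))
})

test_that("a pretrained adapter trains a linear head over external features", {
  # trivial external encoder: normalized letter histogram
  enc <- function(text) {
    h <- table(factor(strsplit(gsub("[^a-z]", "", tolower(text)), "")[[1]],
                      levels = letters))
    as.numeric(h) / max(sum(h), 1)
  }
  tr <- separable_corpus(120)
  dv <- separable_corpus(30, offset = 1000)
  spec <- encoder_spec("pretrained_adapter", encode_fn = enc, adapter_dim = 26L)
  m <- train_supervised(tr, dv, spec,
                        train_config(epochs = 20, learning_rate = 5e-2), seed = 1)
  expect_gte(max(m$history$dev_accuracy), 0.8)
})
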