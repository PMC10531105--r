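# helper: tokenizer + tiny MLM whose vocabulary covers the prompt machinery
prompt_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- shared_corpus()
      ps <- prompt_spec()
      tok <- build_tokenizer(co$conclusion_text[co$split == "train"],
                             extra_texts = c(ps$template, ps$phrases))
      mlm <- tiny_mlm(tok, embedding_dim = 16L, n_layers = 1L, n_heads = 2L,
                      ff_dim = 32L, max_seq_len = 96L, seed = 1)
      cache <<- list(corpus = co, spec = ps, tokenizer = tok, mlm = mlm)
    }
    cache
  }
})

# an MLM whose mask-position distribution ignores the input: zero output
# weights, bias only -> controllable token probabilities
biased_mlm <- function(base, boost_tokens = NULL, boost = 12) {
  base$params$Wv[] <- 0
  base$params$bv[] <- 0
  if (!is.null(boost_tokens)) base$params$bv[boost_tokens] <- boost
  base
}

test_that("prompt specs validate their template and verbalizer", {
  expect_error(prompt_spec("no placeholders here"), "INPUT_TEXT")
  expect_error(prompt_spec("[INPUT_TEXT] [SEP] [MASK] [MASK]"), "exactly once")
  expect_error(prompt_spec(verbalizer = c("0" = "a", "1" = "b", "2" = "c", "3" = "c")),
               "distinct")
  ps <- prompt_spec()
  expect_identical(unname(ps$phrases["SD"]), "stable disease")
})

test_that("cloze prompts end in the mask span and truncate only the input", {
  fx <- prompt_fixture()
  pr <- build_prompt("Stable disease.", fx$spec, fx$tokenizer, k = 2)
  n <- length(pr$ids)
  expect_identical(pr$ids[(n - 1):n],
                   rep(radresponse:::MASK_ID, 2L))
  expect_identical(pr$mask_pos, c(n - 1L, n))
  pr1 <- build_prompt("Stable disease.", fx$spec, fx$tokenizer, k = 1)
  expect_length(pr1$mask_pos, 1L)
  # overlong input: suffix intact, input truncated from the tail
  long <- paste(rep("stable disease in the liver.", 30), collapse = " ")
  prl <- build_prompt(long, fx$spec, fx$tokenizer, k = 2, max_len = 40)
  expect_length(prl$ids, 40L)
  expect_identical(prl$ids[(40 - 1):40], rep(radresponse:::MASK_ID, 2L))
  expect_error(build_prompt("x", fx$spec, fx$tokenizer, k = 2, max_len = 5),
               "exceeds max_len")
})

test_that("a uniform masked LM scores the four classes uniformly", {
  fx <- prompt_fixture()
  uni <- biased_mlm(fx$mlm)
  pr <- build_prompt("Stable disease.", fx$spec, fx$tokenizer, k = 4)
  p <- score_labels(uni, pr, fx$spec)
  expect_equal(unname(p), rep(0.25, 4), tolerance = 1e-9)
})

test_that("mass on the stable-disease tokens makes SD the argmax", {
  fx <- prompt_fixture()
  ids_sd <- encode_ids(fx$tokenizer, "stable disease")
  oracle <- biased_mlm(fx$mlm, boost_tokens = ids_sd)
  pr <- build_prompt("Liver lesion measured today.", fx$spec, fx$tokenizer, k = 4)
  p <- score_labels(oracle, pr, fx$spec)
  expect_identical(names(p)[which.max(p)], "SD")
})

test_that("permuting the verbalizer permutes the scores identically", {
  fx <- prompt_fixture()
  set.seed(3)
  pr <- build_prompt("New lesion in the liver.", fx$spec, fx$tokenizer, k = 4)
  p1 <- score_labels(fx$mlm, pr, fx$spec)
  swapped <- prompt_spec(verbalizer = c(
    "0" = "partial response", "1" = "no evidence of disease",
    "2" = "stable disease", "3" = "progressive disease"))
  p2 <- score_labels(fx$mlm, pr, swapped)
  expect_equal(unname(p2[c("PR", "NED", "SD", "PD")]),
               unname(p1[c("NED", "PR", "SD", "PD")]), tolerance = 1e-12)
})

test_that("decoupled label loss matches the closed-form uniform case", {
  # 10-token vocabulary (6 words + 4 specials), single-token verbalizers
  words <- c("apple", "berry", "cedar", "delta", "ember", "fig")
  tok <- build_tokenizer(paste(words, collapse = " "))
  expect_length(tok$vocab, 10L)
  ps <- prompt_spec(verbalizer = c("0" = "apple", "1" = "berry",
                                   "2" = "cedar", "3" = "delta"))
  mlm <- tiny_mlm(tok, embedding_dim = 8L, n_layers = 1L, n_heads = 2L,
                  ff_dim = 16L, max_seq_len = 32L, seed = 1)
  uni <- biased_mlm(mlm)
  pr <- build_prompt("ember fig", ps, tok, k = 1)
  loss <- decoupled_label_loss(uni, pr, ps, "NED")
  expect_equal(loss, -(log(0.1) + 3 * log(0.9)) / 4, tolerance = 1e-9)
  expect_equal(loss, 0.6546667, tolerance = 1e-6)
})

test_that("one gradient step reduces the decoupled label loss", {
  fx <- prompt_fixture()
  mlm <- fx$mlm
  pr <- build_prompt("Stable liver lesion.", fx$spec, fx$tokenizer, k = 4)
  before <- radresponse:::dll_impl(mlm, pr, fx$spec, "SD", 4, grad = TRUE)
  mlm$params <- radresponse:::tree_map2(function(p, g) p - 0.05 * g,
                                        mlm$params,
                                        radresponse:::mlm_bwd(mlm, before$fwd, before$dLogits))
  after <- decoupled_label_loss(mlm, pr, fx$spec, "SD")
  expect_lt(after, before$loss)
})

test_that("label-conditioned MLM loss has closed forms under a uniform model", {
  fx <- prompt_fixture()
  uni <- biased_mlm(fx$mlm)
  V <- length(fx$tokenizer$vocab)
  pr <- build_prompt("Stable liver lesion today.", fx$spec, fx$tokenizer, k = 4)
  l_true <- label_conditioned_mlm_loss(uni, pr, fx$spec, "SD", "SD",
                                       mask_ratio = 0.9, seed = 5)
  l_false <- label_conditioned_mlm_loss(uni, pr, fx$spec, "PD", "SD",
                                        mask_ratio = 0.9, seed = 5)
  expect_equal(l_true, log(V), tolerance = 1e-9)
  expect_equal(l_false, -log(1 - 1 / V), tolerance = 1e-9)
  expect_error(label_conditioned_mlm_loss(uni, pr, fx$spec, "SD", "SD",
                                          mask_ratio = 0, seed = 1),
               "no input tokens were masked")
})

test_that("prompt training accounting: zero batches and trace length", {
  fx <- prompt_fixture()
  co <- fx$corpus
  tr <- few_shot_sample(co[co$split == "train", ], 30, seed = 1)
  dv <- co[co$split == "dev", ][1:10, ]
  same <- train_prompt(fx$mlm, tr, dv, fx$spec,
                       prompt_train_config(num_batches = 0))
  expect_identical(same$mlm$params, fx$mlm$params)
  expect_identical(nrow(same$trace), 0L)
  out <- train_prompt(fx$mlm, tr, dv, fx$spec,
                      prompt_train_config(num_batches = 60, eval_every = 20,
                                          learning_rate = 1e-3, seed = 2))
  expect_identical(nrow(out$trace), 3L)  # floor(60 / 20)
})

test_that("brief prompt training improves dev accuracy on synthetic data", {
  fx <- prompt_fixture()
  co <- fx$corpus
  tr <- few_shot_sample(co[co$split == "train", ], 60, seed = 1)
  dv <- co[co$split == "dev", ]
  mlm <- pretrain_mlm(fx$mlm, co$conclusion_text[co$split == "train"],
                      steps = 150, seed = 1)
  pre_acc <- evaluate(prompt_predict(mlm, dv, fx$spec), dv$label)$accuracy
  out <- train_prompt(mlm, tr, dv, fx$spec,
                      prompt_train_config(num_batches = 250,
                                          learning_rate = 1e-3,
                                          eval_every = 50, seed = 1))
  post_acc <- evaluate(prompt_predict(out$mlm, dv, fx$spec, out$k), dv$label)$accuracy
  expect_gt(post_acc, pre_acc)
})

test_that("few-shot sampling is stratified by largest remainder", {
  lab <- rep(response_levels(), c(390, 114, 144, 352))
  co <- corpus(paste0("r", seq_along(lab)), paste0("p", seq_along(lab)),
               rep("Stable disease.", length(lab)), lab)
  sub <- few_shot_sample(co, 100, seed = 4)
  cnt <- as.integer(table(factor(sub$label, response_levels())))
  expect_identical(sum(cnt), 100L)
  # quotas 39.0 / 11.4 / 14.4 / 35.2: every count within 1 of its quota
  expect_true(all(abs(cnt - c(39, 11.4, 14.4, 35.2)) <= 1))
  expect_identical(few_shot_sample(co, nrow(co), seed = 1), co)
  s1 <- few_shot_sample(co, 50, seed = 9)
  s2 <- few_shot_sample(co, 50, seed = 9)
  expect_identical(s1$report_id, s2$report_id)
  expect_error(few_shot_sample(co, nrow(co) + 1), "exceeds")
})
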