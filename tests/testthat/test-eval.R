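test_that("evaluation handles the identity and a worked confusion example", {
  r <- evaluate(c("NED", "PR", "SD", "PD"), c("NED", "PR", "SD", "PD"))
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$f1 == 1))

  r2 <- evaluate(c("NED", "PR", "SD", "SD"), c("NED", "PR", "SD", "PD"))
  expect_equal(r2$accuracy, 0.75)
  expect_identical(r2$confusion["PD", "SD"], 1L)
  expect_error(evaluate(c("NED"), c("NED", "PD")), "length mismatch")
})

test_that("accuracy equals micro precision, recall and F1 on random cases", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    gold <- sample(response_levels(), n, replace = TRUE)
    pred <- sample(response_levels(), n, replace = TRUE)
    r <- evaluate(pred, gold)
    expect_equal(r$micro$precision, r$accuracy)
    expect_equal(r$micro$recall, r$accuracy)
    expect_equal(r$micro$f1, r$accuracy)
    expect_identical(sum(r$confusion), as.integer(n))
    # brute-force accuracy from the confusion trace
    expect_equal(sum(diag(r$confusion)) / n, r$accuracy)
  }
})

test_that("run aggregation reports mean and sample standard deviation", {
  mk <- function(a) structure(list(accuracy = a), class = "eval_result")
  rs <- aggregate_runs(list(mk(0.8), mk(0.9), mk(1.0)))
  expect_equal(rs$mean_accuracy, 0.9)
  expect_equal(rs$sd_accuracy, sd(c(0.8, 0.9, 1.0)))
  expect_true(rs$mean_accuracy >= min(rs$accuracies) &&
                rs$mean_accuracy <= max(rs$accuracies))
  expect_equal(aggregate_runs(list(mk(0.7)))$sd_accuracy, 0)
  expect_error(aggregate_runs(list()), "empty")
})

test_that("paired t-test matches hand computation and flags degenerate cases", {
  eq <- paired_t_test(c(0.8, 0.9), c(0.8, 0.9))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_true(eq$degenerate)

  const <- paired_t_test(c(0.82, 0.84, 0.86), c(0.80, 0.82, 0.84))
  expect_true(const$degenerate)
  expect_true(is.na(const$p))

  tt <- paired_t_test(c(0.85, 0.88, 0.86), c(0.80, 0.82, 0.81))
  expect_false(tt$degenerate)
  expect_equal(tt$t, 16, tolerance = 1e-9)       # mean(d) / (sd(d) / sqrt(3))
  expect_equal(tt$p, 0.00388351, tolerance = 1e-6)
  expect_identical(tt$df, 2)
})

test_that("Cohen's kappa matches the worked 2x2 table and chance behavior", {
  expect_equal(cohen_kappa(c("NED", "PD", "SD"), c("NED", "PD", "SD")), 1)
  # 2x2 table a=40, b=10, c=10, d=40: (0.8 - 0.5) / 0.5 = 0.6
  a <- rep(c("NED", "NED", "PD", "PD"), c(40, 10, 10, 40))
  b <- rep(c("NED", "PD", "NED", "PD"), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(a, b), 0.6)
  set.seed(17)
  x <- sample(response_levels(), 10000, replace = TRUE)
  y <- sample(response_levels(), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(x, y)), 0.05)
  # invariant under consistent relabeling
  relab <- c(NED = "PD", PR = "SD", SD = "PR", PD = "NED")
  expect_equal(cohen_kappa(relab[x], relab[y]), cohen_kappa(x, y))
})

test_that("Spearman's rho handles ties by mid-ranks", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # frozen from the mid-rank Pearson formula on ranks (1, 2.5, 2.5, 4) and
  # (1, 2, 3.5, 3.5)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 3)), 0.8333333,
               tolerance = 1e-6)
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 2, 3))))
  # invariant under monotone transformation
  set.seed(5)
  x <- runif(30); y <- runif(30)
  expect_equal(spearman_rho(exp(3 * x), y), spearman_rho(x, y))
})

test_that("learning curves reduce to a direct run at full size and are reproducible", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:120, ]
  te <- co[co$split == "test", ][1:40, ]
  trainer <- function(sub, seed) {
    m <- fit_classical(sub, kind = "logreg", seed = seed)
    function(texts) predict(m, texts, type = "class")
  }
  lc <- learning_curve(trainer, tr, te, sizes = c(40L, nrow(tr)), seeds = 1L)
  expect_identical(nrow(lc), 2L)
  direct <- trainer(tr, 1L)
  expect_equal(lc$mean_accuracy[2],
               evaluate(direct(te$conclusion_text), te$label)$accuracy)
  lc2 <- learning_curve(trainer, tr, te, sizes = c(40L, nrow(tr)), seeds = 1L)
  expect_identical(lc, lc2)
  expect_error(learning_curve(trainer, tr, te, sizes = 10 * nrow(tr)), "exceeds")
})

test_that("saliency weights are normalized and rendered token-for-token", {
  co <- shared_corpus()
  tr <- co[co$split == "train", ][1:30, ]
  dv <- co[co$split == "dev", ][1:10, ]
  m <- train_supervised(tr, dv, tiny_tf_spec(), train_config(epochs = 1), seed = 1)
  txt <- "New lesion in the liver."
  sal <- saliency(m, txt)
  expect_length(sal$weights, length(sal$tokens))
  expect_true(all(sal$weights >= 0 & sal$weights <= 1))
  html <- render_saliency(sal)
  expect_identical(lengths(regmatches(html, gregexpr("<span", html))),
                   length(sal$tokens))
  # single-token input: min-max degenerates to weight 1
  expect_equal(saliency(m, "stable")$weights, 1)
  # gradient x input works for any architecture; attention does not
  mc <- train_supervised(tr, dv,
                         encoder_spec("cnn", embedding_dim = 8L, n_filters = 6L,
                                      dense_units = 6L, max_seq_len = 32L),
                         train_config(epochs = 1), seed = 1)
  expect_error(saliency(mc, txt), "transformer")
  expect_length(saliency(mc, txt, method = "grad_input")$tokens,
                length(sal$tokens))
})
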