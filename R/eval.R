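# Evaluation harness: multiclass metrics (with the accuracy == micro-F1
# identity of single-label classification), multi-seed aggregation, paired
# t-tests, learning curves and agreement statistics.

#' Evaluate predictions against gold labels
#'
#' Computes the 4x4 confusion matrix (rows = gold, columns = predicted),
#' accuracy, micro- and macro-averaged precision/recall/F1 and per-class
#' metrics. In single-label multiclass classification accuracy equals
#' micro-F1, micro-precision and micro-recall; a class with no gold members
#' and no predictions has per-class F1 defined as 0.
#'
#' @param predictions,gold Equal-length label vectors (names or codes).
#' @return An object of class `eval_result`.
#' @export
evaluate <- function(predictions, gold) {
  predictions <- as_response_label(predictions)
  gold <- as_response_label(gold)
  if (!length(gold)) stop("empty evaluation")
  if (length(predictions) != length(gold)) stop("length mismatch")
  lv <- response_levels()
  cm <- table(factor(gold, levels = lv), factor(predictions, levels = lv))
  cm <- matrix(as.integer(cm), 4, 4, dimnames = list(gold = lv, predicted = lv))
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  micro_p <- sum(tp) / (sum(tp) + sum(fp))
  micro_r <- sum(tp) / (sum(tp) + sum(fn))
  structure(list(
    accuracy = sum(tp) / n,
    micro = list(precision = micro_p, recall = micro_r,
                 f1 = if (micro_p + micro_r > 0) {
                   2 * micro_p * micro_r / (micro_p + micro_r)
                 } else 0),
    macro_f1 = mean(f1),
    per_class = data.frame(label = lv, precision = prec, recall = rec, f1 = f1,
                           support = rowSums(cm), row.names = NULL),
    confusion = cm,
    n = n
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n=%d accuracy=%.4f (== micro-F1) macro-F1=%.4f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Aggregate evaluation results over random seeds
#'
#' @param results List of `eval_result` objects (>= 1), one per seed.
#' @return List with per-run accuracies, their mean and sample standard
#'   deviation (0 for a single run).
#' @export
aggregate_runs <- function(results) {
  if (!length(results)) stop("empty result list")
  acc <- vapply(results, function(r) r$accuracy, numeric(1))
  list(accuracies = acc, mean_accuracy = mean(acc),
       sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else 0,
       n_runs = length(acc))
}

#' Paired t-test on per-unit accuracies
#'
#' Classical paired t with n - 1 degrees of freedom, pairing units (typically
#' seeds) across two systems. Degenerate cases are flagged rather than
#' computed: identical vectors give t = 0, p = 1; a constant non-zero
#' difference has undefined p (zero variance).
#'
#' @param a,b Equal-length numeric vectors (n >= 2), paired by unit.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 paired units")
  d <- a - b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Accuracy as a function of training-set size
#'
#' For each size, draws a stratified [few_shot_sample()] of the training
#' records, calls `trainer` on it, and evaluates the returned prediction
#' function on the fixed test records; seeds are crossed with sizes so the
#' curve is reproducible bit-for-bit.
#'
#' @param trainer Function `(train_corpus, seed) -> function(texts) -> labels`.
#' @param train A `response_corpus` of training records.
#' @param test A `response_corpus` of evaluation records.
#' @param sizes Ascending integer vector of training sizes (<= nrow(train)).
#' @param seeds Integer vector of seeds (default 1:3).
#' @return Data frame with columns `size`, `mean_accuracy`, `sd_accuracy`.
#' @export
learning_curve <- function(trainer, train, test, sizes, seeds = c(1L, 2L, 3L)) {
  train <- validate_corpus(train)
  test <- validate_corpus(test)
  if (any(sizes > nrow(train))) stop("size exceeds corpus")
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  rows <- lapply(sizes, function(sz) {
    acc <- vapply(seeds, function(sd) {
      sub <- few_shot_sample(train, sz, seed = sd)
      predict_fn <- trainer(sub, sd)
      evaluate(predict_fn(test$conclusion_text), test$label)$accuracy
    }, numeric(1))
    data.frame(size = sz, mean_accuracy = mean(acc),
               sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else 0)
  })
  do.call(rbind, rows)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement computed from the two raters' marginals. Returns NA with a
#' degenerate flag when chance agreement is 1 (both raters constant and
#' identical marginals).
#'
#' @param rater_a,rater_b Equal-length label vectors (>= 2 items).
#' @return Kappa in [-1, 1] (scalar), or NA if degenerate.
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) stop("length mismatch")
  if (length(rater_a) < 2L) stop("need at least 2 items")
  lv <- union(unique(rater_a), unique(rater_b))
  a <- factor(rater_a, levels = lv)
  b <- factor(rater_b, levels = lv)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Spearman rank correlation with mid-rank ties
#'
#' @param x,y Equal-length ordinal vectors (n >= 3).
#' @return Rho in [-1, 1], or NA if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 items")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(as.numeric(x), as.numeric(y), method = "spearman")
}

#' Original-vs-permuted prediction divergence
#'
#' Mean consistency loss between a classifier's label distributions on each
#' record and on one sentence-permuted variant of it — the quantity the
#' consistency-training objective drives down on held-out data. Records whose
#' conclusion has a single sentence are skipped.
#'
#' @param model A `neural_classifier` (anything accepted by [predict_proba()]).
#' @param x A `response_corpus`.
#' @param seed Integer seed for the variant draws.
#' @return Mean divergence (scalar).
#' @export
prediction_divergence <- function(model, x, seed = 1L) {
  x <- validate_corpus(x)
  vals <- vapply(seq_len(nrow(x)), function(i) {
    v <- permute_conclusion(x$conclusion_text[i], P = 1L, seed = seed + i)
    if (!length(v)) return(NA_real_)
    p1 <- predict_proba(model, x$conclusion_text[i])[1L, ]
    p2 <- predict_proba(model, v[[1L]]$text)[1L, ]
    consistency_loss(p1, p2)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
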