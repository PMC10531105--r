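# Cloze-prompt few-shot fine-tuning. A conclusion text is wrapped in the
# prompt "[INPUT_TEXT] [SEP] In summary, this is a [MASK]", the masked span is
# scored against the verbalizer phrases of the four response classes, and the
# masked LM is fine-tuned by minimizing the sum of a decoupled label loss
# (binary cross-entropy on candidate label tokens at the mask span) and a
# label-conditioned masked-LM loss (masked-token reconstruction with targets
# inverted when the candidate label is wrong).

.default_verbalizer <- c("0" = "no evidence of disease",
                         "1" = "partial response",
                         "2" = "stable disease",
                         "3" = "progressive disease")

#' Define a cloze prompt and verbalizer
#'
#' @param template Template string containing each of `[INPUT_TEXT]`, `[SEP]`
#'   and `[MASK]` exactly once.
#' @param verbalizer Named character vector mapping class codes "0".."3" (or
#'   label names) to pairwise-distinct label phrases.
#' @return A `prompt_spec` object.
#' @export
prompt_spec <- function(template = "[INPUT_TEXT] [SEP] In summary, this is a [MASK]",
                        verbalizer = .default_verbalizer) {
  for (ph in c("[INPUT_TEXT]", "[SEP]", "[MASK]")) {
    n <- lengths(regmatches(template, gregexpr(ph, template, fixed = TRUE)))
    if (n != 1L) stop("template must contain ", ph, " exactly once")
  }
  if (length(verbalizer) != 4L) stop("verbalizer must cover all four classes")
  codes <- label_code(as_response_label(names(verbalizer)))
  if (!setequal(codes, 0:3)) stop("verbalizer must cover codes 0..3")
  phrases <- as.character(verbalizer)[order(codes)]
  if (anyDuplicated(tolower(phrases))) stop("verbalizer phrases must be distinct")
  structure(list(template = template, phrases = setNames(phrases, response_levels())),
            class = "prompt_spec")
}

#' Training configuration for prompt-based fine-tuning
#'
#' Defaults follow the reference recipe: 2000 batches, learning rate 1e-5,
#' evaluation every 100 batches. `max_label_tokens = NULL` uses the longest
#' tokenized verbalization (so multi-token phrases are never truncated); the
#' value 2 of the reference recipe is selectable.
#'
#' @param num_batches Gradient steps (default 2000).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param eval_every Dev evaluation period in batches (default 100).
#' @param max_label_tokens Length of the mask span; NULL = longest
#'   verbalization.
#' @param mask_ratio Input-token masking rate of the label-conditioned MLM
#'   loss (default 0.15).
#' @param seed Integer seed.
#' @return A `prompt_train_config` list.
#' @export
prompt_train_config <- function(num_batches = 2000L, learning_rate = 1e-5,
                                eval_every = 100L, max_label_tokens = NULL,
                                mask_ratio = 0.15, seed = 1L) {
  if (num_batches < 0L || eval_every < 1L || learning_rate <= 0) {
    stop("invalid prompt_train_config")
  }
  if (!is.null(max_label_tokens) && max_label_tokens < 1L) {
    stop("max_label_tokens must be >= 1")
  }
  structure(list(num_batches = as.integer(num_batches),
                 learning_rate = learning_rate,
                 eval_every = as.integer(eval_every),
                 max_label_tokens = max_label_tokens,
                 mask_ratio = mask_ratio, seed = as.integer(seed)),
            class = "prompt_train_config")
}

# tokenized verbalizations as a 4 x k id matrix (PAD-filled, PAD excluded from
# scoring and losses)
verbalizer_ids <- function(spec, tokenizer, k = NULL) {
  idlist <- lapply(spec$phrases, function(ph) {
    ids <- encode_ids(tokenizer, ph)
    if (!length(ids)) stop("verbalization tokenizes to 0 tokens: ", ph)
    ids
  })
  if (is.null(k)) k <- max(lengths(idlist))
  M <- matrix(PAD_ID, 4L, k)
  for (i in 1:4) {
    ids <- idlist[[i]]
    M[i, seq_len(min(k, length(ids)))] <- ids[seq_len(min(k, length(ids)))]
  }
  M
}

#' Build a cloze-prompt token sequence
#'
#' Substitutes the input text into the template, expands `[MASK]` into a span
#' of `k` mask tokens, and truncates the input text from the tail — never the
#' prompt suffix — to respect `max_len`.
#'
#' @param text Conclusion text.
#' @param spec A [prompt_spec()].
#' @param tokenizer A `radr_tokenizer`.
#' @param k Mask-span length.
#' @param max_len Maximum total sequence length.
#' @return List with `ids` (integer sequence), `mask_pos` (the k mask
#'   positions) and `input_pos` (positions of the input-text tokens).
#' @export
build_prompt <- function(text, spec, tokenizer, k, max_len = Inf) {
  stopifnot(inherits(spec, "prompt_spec"), k >= 1L)
  parts <- strsplit(spec$template, "[INPUT_TEXT]", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  seg_ids <- function(seg) {
    out <- integer(0)
    mask_at <- integer(0)
    pieces <- strsplit(gsub("\\[(SEP|MASK)\\]", " [\\1] ", seg), "\\s+")[[1]]
    pieces <- pieces[nzchar(pieces)]
    for (p in pieces) {
      if (p == "[SEP]") {
        out <- c(out, SEP_ID)
      } else if (p == "[MASK]") {
        mask_at <- c(mask_at, length(out) + seq_len(k))
        out <- c(out, rep(MASK_ID, k))
      } else {
        out <- c(out, encode_ids(tokenizer, p))
      }
    }
    list(ids = out, mask_at = mask_at)
  }
  pre <- seg_ids(parts[1])
  suf <- seg_ids(parts[2])
  input_ids <- encode_ids(tokenizer, text)
  fixed_len <- length(pre$ids) + length(suf$ids)
  if (fixed_len > max_len) stop("prompt template alone exceeds max_len")
  room <- max_len - fixed_len
  if (length(input_ids) > room) input_ids <- input_ids[seq_len(room)]
  ids <- c(pre$ids, input_ids, suf$ids)
  mask_pos <- c(pre$mask_at, length(pre$ids) + length(input_ids) + suf$mask_at)
  list(ids = ids, mask_pos = mask_pos,
       input_pos = length(pre$ids) + seq_along(input_ids))
}

#' Score the four classes at the mask span
#'
#' Each class is scored by the mean log-probability of its tokenized
#' verbalization (padded/truncated to the span length; padded positions
#' excluded) under the masked LM at the mask positions; scores are normalized
#' over classes with a softmax. Length normalization keeps shorter
#' verbalizations from being favored.
#'
#' @param mlm A `tiny_mlm` (or any object supported by `mlm_fwd`).
#' @param prompt Output of [build_prompt()].
#' @param spec A [prompt_spec()].
#' @param k Mask-span length (must match the prompt).
#' @return Probability 4-vector over NED/PR/SD/PD.
#' @export
score_labels <- function(mlm, prompt, spec, k = length(prompt$mask_pos)) {
  vb <- verbalizer_ids(spec, mlm$tokenizer, k)
  fwd <- mlm_fwd(mlm, prompt$ids)
  lp <- log(fwd$probs[prompt$mask_pos, , drop = FALSE] + 1e-12)
  scores <- vapply(1:4, function(c_) {
    tok <- vb[c_, ]
    use <- which(tok != PAD_ID)
    mean(lp[cbind(use, tok[use])])
  }, numeric(1))
  setNames(softmax_vec(scores), response_levels())
}

# decoupled label loss: BCE over candidate-label tokens at the mask span.
# Returns value and, when grad = TRUE, the dLogits matrix for mlm_bwd.
dll_impl <- function(mlm, prompt, spec, true_label, k, grad = FALSE,
                     full_vocab_negatives = FALSE) {
  vb <- verbalizer_ids(spec, mlm$tokenizer, k)
  fwd <- mlm_fwd(mlm, prompt$ids)
  eps <- 1e-7
  true_row <- label_code(true_label) + 1L
  loss <- 0
  n_pairs <- 0L
  dLogits <- if (grad) matrix(0, length(prompt$ids), ncol(fwd$logits)) else NULL
  for (j in seq_len(k)) {
    pos <- prompt$mask_pos[j]
    p <- fwd$probs[pos, ]
    dp <- numeric(length(p))
    cand <- if (full_vocab_negatives) seq_along(p) else unique(vb[, j])
    for (tok in cand) {
      if (tok == PAD_ID) next
      y <- as.numeric(tok %in% vb[true_row, j] && vb[true_row, j] != PAD_ID)
      if (full_vocab_negatives || tok %in% vb[, j]) {
        pt <- min(max(p[tok], eps), 1 - eps)
        loss <- loss - (y * log(pt) + (1 - y) * log(1 - pt))
        n_pairs <- n_pairs + 1L
        if (grad) dp[tok] <- dp[tok] + (-y / pt + (1 - y) / (1 - pt))
      }
    }
    if (grad && any(dp != 0)) {
      dLogits[pos, ] <- dLogits[pos, ] + softmax_vjp(p, dp)
    }
  }
  loss <- loss / max(n_pairs, 1L)
  if (grad) dLogits <- dLogits / max(n_pairs, 1L)
  list(loss = loss, dLogits = dLogits, fwd = fwd)
}

#' Decoupled label loss at the mask span
#'
#' Per-token binary cross-entropy over the candidate verbalizations: the true
#' label's tokens are pushed toward probability 1 and the competing labels'
#' tokens toward 0, averaged over the involved (position, token) pairs.
#' By default the negative set is restricted to the other candidate labels'
#' tokens; `full_vocab_negatives = TRUE` extends it to the whole vocabulary.
#'
#' @inheritParams score_labels
#' @param true_label The record's response label.
#' @param full_vocab_negatives Use every vocabulary token as a negative.
#' @return Non-negative scalar loss.
#' @export
decoupled_label_loss <- function(mlm, prompt, spec, true_label,
                                 k = length(prompt$mask_pos),
                                 full_vocab_negatives = FALSE) {
  dll_impl(mlm, prompt, spec, true_label, k,
           full_vocab_negatives = full_vocab_negatives)$loss
}

lcm_impl <- function(mlm, prompt, spec, candidate, true_label, mask_ratio,
                     grad = FALSE, ensure_one = FALSE) {
  k <- length(prompt$mask_pos)
  vb <- verbalizer_ids(spec, mlm$tokenizer, k)
  cand_row <- label_code(candidate) + 1L
  ids <- prompt$ids
  ids[prompt$mask_pos] <- vb[cand_row, ]
  if (!length(prompt$input_pos)) stop("no input tokens available for masking")
  maskpos <- prompt$input_pos[stats::runif(length(prompt$input_pos)) < mask_ratio]
  if (!length(maskpos)) {
    maskpos <- prompt$input_pos[stats::runif(length(prompt$input_pos)) < mask_ratio]
    if (!length(maskpos)) {
      if (!ensure_one) stop("no input tokens were masked after resampling")
      maskpos <- prompt$input_pos[sample.int(length(prompt$input_pos), 1L)]
    }
  }
  orig <- prompt$ids[maskpos]
  ids[maskpos] <- MASK_ID
  fwd <- mlm_fwd(mlm, ids)
  eps <- 1e-7
  y <- as.numeric(as_response_label(candidate) == as_response_label(true_label))
  loss <- 0
  dLogits <- if (grad) matrix(0, length(ids), ncol(fwd$logits)) else NULL
  for (m in seq_along(maskpos)) {
    pos <- maskpos[m]
    p <- fwd$probs[pos, ]
    pt <- min(max(p[orig[m]], eps), 1 - eps)
    loss <- loss - (y * log(pt) + (1 - y) * log(1 - pt))
    if (grad) {
      dp <- numeric(length(p))
      dp[orig[m]] <- (-y / pt + (1 - y) / (1 - pt)) / length(maskpos)
      dLogits[pos, ] <- softmax_vjp(p, dp)
    }
  }
  list(loss = loss / length(maskpos), dLogits = dLogits, fwd = fwd)
}

#' Label-conditioned masked-LM loss
#'
#' The mask span is filled with the candidate label's verbalization, a
#' fraction `mask_ratio` of the input-text tokens is masked, and the model
#' reconstructs the original tokens. The per-token binary cross-entropy target
#' is 1 when the candidate is the record's true label and 0 otherwise, so the
#' model learns to reproduce the text only under the correct label. Errors if
#' no token is masked after one resampling attempt.
#'
#' @inheritParams decoupled_label_loss
#' @param candidate The candidate label conditioning the reconstruction.
#' @param mask_ratio Masking probability per input token.
#' @param seed Integer seed for the masking draw.
#' @return Non-negative scalar loss.
#' @export
label_conditioned_mlm_loss <- function(mlm, prompt, spec, candidate, true_label,
                                       mask_ratio = 0.15, seed = 1L) {
  set.seed(as.integer(seed))
  lcm_impl(mlm, prompt, spec, candidate, true_label, mask_ratio)$loss
}

#' Stratified few-shot subsample of a corpus
#'
#' Samples exactly `n_reports` records at the report level, stratified by
#' class with largest-remainder apportionment of the corpus class proportions.
#'
#' @param x A `response_corpus`.
#' @param n_reports Number of records to keep (<= corpus size).
#' @param seed Integer seed.
#' @return A `response_corpus` of `n_reports` records.
#' @export
few_shot_sample <- function(x, n_reports, seed = 1L) {
  x <- validate_corpus(x)
  if (n_reports > nrow(x)) stop("n_reports exceeds corpus size")
  if (n_reports == nrow(x)) return(x)
  cnt <- table(factor(x$label, levels = response_levels()))
  target <- apportion(n_reports, as.numeric(cnt) / nrow(x))
  # classes absent from the corpus cannot contribute; reapportion over present
  for (i in which(as.numeric(cnt) < target)) {
    target[i] <- as.numeric(cnt)[i]
  }
  while (sum(target) < n_reports) {
    room <- which(as.numeric(cnt) > target)
    target[room[1]] <- target[room[1]] + 1L
  }
  set.seed(as.integer(seed))
  keep <- integer(0)
  for (i in 1:4) {
    pool <- which(x$label == response_levels()[i])
    if (target[i] > 0L) keep <- c(keep, pool[sample.int(length(pool), target[i])])
  }
  x[sort(keep), , drop = FALSE]
}

#' Prompt-based fine-tuning of a masked LM
#'
#' Minimizes the sum of the decoupled label loss and the label-conditioned
#' masked-LM loss (averaged over the true label and one sampled wrong
#' candidate) over `num_batches` single-example gradient steps, evaluating dev
#' accuracy every `eval_every` batches and returning the best-dev state.
#'
#' @param mlm A `tiny_mlm` (typically pre-trained with [pretrain_mlm()]).
#' @param train,dev Patient-disjoint `response_corpus` objects.
#' @param spec A [prompt_spec()].
#' @param config A [prompt_train_config()].
#' @return List with `mlm` (best-dev state), `trace` (data frame batch /
#'   dev_accuracy, one row per evaluation) and `k` (mask-span length used).
#' @export
train_prompt <- function(mlm, train, dev, spec = prompt_spec(),
                         config = prompt_train_config()) {
  stopifnot(inherits(mlm, "tiny_mlm"))
  train <- validate_corpus(train)
  dev <- validate_corpus(dev)
  check_patient_disjoint(train, dev)
  if (!nrow(train)) stop("empty training corpus")
  k <- if (is.null(config$max_label_tokens)) {
    max(lengths(lapply(spec$phrases, encode_ids, tokenizer = mlm$tokenizer)))
  } else config$max_label_tokens
  trace <- data.frame(batch = integer(0), dev_accuracy = numeric(0))
  if (config$num_batches == 0L) return(list(mlm = mlm, trace = trace, k = k))
  set.seed(config$seed)
  state <- adam_init(mlm$params)
  prompts <- lapply(train$conclusion_text, build_prompt, spec = spec,
                    tokenizer = mlm$tokenizer, k = k, max_len = mlm$max_seq_len)
  dev_prompts <- lapply(dev$conclusion_text, build_prompt, spec = spec,
                        tokenizer = mlm$tokenizer, k = k, max_len = mlm$max_seq_len)
  best_acc <- -Inf
  best_params <- mlm$params
  for (b in seq_len(config$num_batches)) {
    i <- sample.int(nrow(train), 1L)
    truth <- train$label[i]
    d1 <- dll_impl(mlm, prompts[[i]], spec, truth, k, grad = TRUE)
    g <- mlm_bwd(mlm, d1$fwd, d1$dLogits)
    wrong <- sample(setdiff(response_levels(), truth), 1L)
    for (cand in c(truth, wrong)) {
      lc <- lcm_impl(mlm, prompts[[i]], spec, cand, truth, config$mask_ratio,
                     grad = TRUE, ensure_one = TRUE)
      g <- tree_add(g, mlm_bwd(mlm, lc$fwd, tree_map(function(x) x / 2, lc$dLogits)))
    }
    st <- adam_step(mlm$params, g, state, config$learning_rate)
    mlm$params <- st$params
    state <- st$state
    if (b %% config$eval_every == 0L) {
      acc <- mean(vapply(seq_len(nrow(dev)), function(j) {
        p <- score_labels(mlm, dev_prompts[[j]], spec, k)
        names(p)[which.max(p)] == dev$label[j]
      }, logical(1)))
      trace <- rbind(trace, data.frame(batch = b, dev_accuracy = acc))
      if (acc > best_acc) {
        best_acc <- acc
        best_params <- mlm$params
      }
    }
  }
  mlm$params <- best_params
  list(mlm = mlm, trace = trace, k = k)
}

#' Classify texts with a prompted masked LM
#'
#' @param mlm A `tiny_mlm`.
#' @param texts Character vector or `response_corpus`.
#' @param spec A [prompt_spec()].
#' @param k Mask-span length (NULL = longest verbalization).
#' @return Character vector of predicted labels.
#' @export
prompt_predict <- function(mlm, texts, spec = prompt_spec(), k = NULL) {
  if (inherits(texts, "response_corpus")) texts <- texts$conclusion_text
  if (is.null(k)) {
    k <- max(lengths(lapply(spec$phrases, encode_ids, tokenizer = mlm$tokenizer)))
  }
  vapply(texts, function(tx) {
    pr <- build_prompt(tx, spec, mlm$tokenizer, k, mlm$max_seq_len)
    p <- score_labels(mlm, pr, spec, k)
    names(p)[which.max(p)]
  }, character(1), USE.NAMES = FALSE)
}

#' Head-only fine-tuning baseline on a frozen encoder
#'
#' The comparator for prompt-based fine-tuning: the masked LM's encoder is
#' frozen, each text is represented by its mean-pooled final hidden state, and
#' a multinomial logistic head is fitted on those features.
#'
#' @param mlm A `tiny_mlm` used as a frozen feature extractor.
#' @param train A `response_corpus`.
#' @param seed Integer seed.
#' @return An object of class `mlm_head_model` with a `predict` method.
#' @export
fit_mlm_head <- function(mlm, train, seed = 1L) {
  stopifnot(inherits(mlm, "tiny_mlm"))
  train <- validate_corpus(train)
  feats <- mlm_pooled_features(mlm, train$conclusion_text)
  set.seed(as.integer(seed))
  y <- factor(train$label, levels = intersect(response_levels(), unique(train$label)))
  fit <- suppressWarnings(
    glmnet::glmnet(feats, y, family = "multinomial", alpha = 0,
                   lambda = 0.01, standardize = FALSE))
  structure(list(mlm = mlm, fit = fit, classes = levels(y)),
            class = "mlm_head_model")
}

mlm_pooled_features <- function(mlm, texts) {
  t(vapply(texts, function(tx) {
    ids <- encode_ids(mlm$tokenizer, tx, mlm$max_seq_len)
    colMeans(mlm_fwd(mlm, ids)$enc$out)
  }, numeric(mlm$d)))
}

#' @export
predict.mlm_head_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  texts <- if (inherits(newdata, "response_corpus")) newdata$conclusion_text
           else as.character(newdata)
  feats <- mlm_pooled_features(object$mlm, texts)
  pr <- stats::predict(object$fit, feats, type = "response")[, , 1]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
  P <- matrix(0, nrow(feats), 4L, dimnames = list(NULL, response_levels()))
  P[, colnames(pr)] <- pr
  if (type == "prob") P else argmax_label(P)
}
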