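# Sentence-permutation augmentation and the consistency-loss objective.
#
# Sentences in a radiology conclusion are largely order-exchangeable, so
# permuting them yields a new, label-preserving training text. For each
# conclusion we draw P distinct non-identity sentence orders; during
# consistency training the model's label distributions on an original and on a
# permuted variant are tied together with a mean-squared-error penalty.

# all permutations of 1..n as a list of integer vectors (n! rows; used for n<=7)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}

#' Generate sentence-permuted variants of a conclusion text
#'
#' Draws up to `P` distinct sentence orders, all different from the identity
#' order and from each other, so an n-sentence conclusion yields exactly
#' `min(P, n! - 1)` variants (0 for single-sentence conclusions). The sentence
#' multiset — and therefore the response label — is preserved by construction.
#' For conclusions with duplicated sentences, variants whose rendered text
#' collides with the original or an earlier variant are dropped and resampled,
#' up to `max_attempts` draws.
#'
#' @param text Conclusion text (character scalar).
#' @param P Maximum number of variants (default 10).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param max_attempts Cap on rejection sampling for long conclusions
#'   (default `100 * P`).
#' @return A list of variants, each a list with elements `order` (permutation
#'   of sentence indices) and `text` (sentences joined in that order).
#' @export
permute_conclusion <- function(text, P = 10L, seed = 1L, max_attempts = 100L * P) {
  if (P < 1L) stop("P must be >= 1")
  sentences <- split_sentences(text)
  n <- length(sentences)
  if (n == 1L) return(list())
  set.seed(as.integer(seed))
  orders <- list()
  if (n <= 7L) {
    perms <- all_perms(n)
    perms <- perms[!vapply(perms, function(p) all(p == seq_len(n)), logical(1))]
    take <- min(P, length(perms))
    orders <- perms[sample.int(length(perms), take)]
  } else {
    seen <- character(0)
    attempts <- 0L
    while (length(orders) < P && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- sample.int(n)
      key <- paste(p, collapse = ",")
      if (all(p == seq_len(n)) || key %in% seen) next
      seen <- c(seen, key)
      orders[[length(orders) + 1L]] <- p
    }
  }
  # drop textual duplicates (possible when sentences are duplicated)
  texts_seen <- join_sentences(sentences)
  out <- list()
  for (p in orders) {
    txt <- join_sentences(sentences[p])
    if (txt %in% texts_seen) next
    texts_seen <- c(texts_seen, txt)
    out[[length(out) + 1L]] <- list(order = p, text = txt)
  }
  out
}

#' Augment a corpus with sentence-permuted variants
#'
#' Applies [permute_conclusion()] to every record; each variant inherits its
#' parent's patient, label and split, and records the parent id and the
#' permutation applied.
#'
#' @param x A `response_corpus`.
#' @param P Variants per record (default 10).
#' @param seed Integer seed.
#' @return A `response_corpus` of variant records with extra columns
#'   `parent_report_id` and `permutation` (comma-separated order).
#' @export
augment_corpus <- function(x, P = 10L, seed = 1L) {
  x <- validate_corpus(x)
  rows <- list()
  for (i in seq_len(nrow(x))) {
    vars <- permute_conclusion(x$conclusion_text[i], P = P,
                               seed = as.integer(seed) + i)
    for (j in seq_along(vars)) {
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = sprintf("%s-perm%02d", x$report_id[i], j),
        patient_id = x$patient_id[i],
        conclusion_text = vars[[j]]$text,
        label = x$label[i],
        split = x$split[i],
        provenance = x$provenance[i],
        parent_report_id = x$report_id[i],
        permutation = paste(vars[[j]]$order, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    out <- x[0, c("report_id", "patient_id", "conclusion_text", "label",
                  "split", "provenance"), drop = FALSE]
    out$parent_report_id <- character(0)
    out$permutation <- character(0)
    return(validate_corpus(out))
  }
  validate_corpus(do.call(rbind, rows))
}

#' Consistency loss between two label distributions
#'
#' Mean over the C = 4 response classes of the squared differences between the
#' model's label distribution on an original text and on a permuted variant:
#' `mean((y - y_p)^2)`. Symmetric, zero iff the distributions agree, and
#' bounded by 0.5 on the probability simplex (attained at orthogonal one-hots).
#'
#' @param y,y_p Numeric probability 4-vectors (non-negative, summing to 1).
#' @return A non-negative scalar.
#' @export
consistency_loss <- function(y, y_p) {
  check_label_distribution(y)
  check_label_distribution(y_p)
  mean((y - y_p)^2)
}

check_label_distribution <- function(p) {
  if (length(p) != 4L) stop("label distribution must have length 4 (C = 4 classes)")
  if (any(p < -1e-9)) stop("label distribution has negative components")
  if (abs(sum(p) - 1) > 1e-6) stop("label distribution must sum to 1")
  invisible(p)
}

#' Combine cross-entropy and consistency losses
#'
#' Total training loss `alpha * ce + beta * mse`; the defaults alpha = 1,
#' beta = 10 weight the consistency penalty ten-fold relative to
#' cross-entropy.
#'
#' @param ce Non-negative cross-entropy loss.
#' @param mse Non-negative consistency (MSE) loss.
#' @param alpha,beta Non-negative weights, not both zero.
#' @return List with components `ce`, `mse`, `total`.
#' @export
total_loss <- function(ce, mse, alpha = 1, beta = 10) {
  if (ce < 0 || mse < 0) stop("loss components must be non-negative")
  if (alpha < 0 || beta < 0) stop("weights must be non-negative")
  if (alpha == 0 && beta == 0) stop("alpha and beta must not both be zero")
  list(ce = ce, mse = mse, total = alpha * ce + beta * mse)
}
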