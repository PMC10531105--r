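# Bag-of-words TF-IDF featurizer for the classical baselines.
#
# n-grams are computed within sentences (never across a sentence boundary), so
# the feature vector of a document is exactly invariant to sentence
# permutation — the property that lets the classical models serve as an oracle
# for the label-preservation claim of the augmentation module.

tokenize_words <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  regmatches(text, gregexpr("[a-z0-9]+", text))[[1]]
}

doc_terms <- function(text, ngram_range, lowercase) {
  sents <- split_sentences(text)
  out <- character(0)
  for (s in sents) {
    toks <- tokenize_words(s, lowercase)
    for (n in seq(ngram_range[1], ngram_range[2])) {
      if (length(toks) >= n) {
        if (n == 1L) {
          out <- c(out, toks)
        } else {
          idx <- seq_len(length(toks) - n + 1L)
          grams <- toks[idx]
          for (k in seq_len(n - 1L)) grams <- paste(grams, toks[idx + k], sep = "_")
          out <- c(out, grams)
        }
      }
    }
  }
  out
}

#' Fit a TF-IDF bag-of-words featurizer
#'
#' Builds a vocabulary of word n-grams (default unigrams + bigrams, bigrams
#' never spanning a sentence boundary), drops terms appearing in fewer than
#' `min_df` documents, and stores smooth inverse document frequencies
#' `log((1 + N) / (1 + df)) + 1`. Transformed vectors are raw term counts
#' scaled by idf and l2-normalized.
#'
#' @param texts Character vector of training documents (>= 2).
#' @param ngram_range Integer pair, default `c(1, 2)`.
#' @param min_df Minimum document frequency, default 2.
#' @param lowercase Lowercase before tokenizing, default TRUE.
#' @return An object of class `tfidf_featurizer`.
#' @export
fit_tfidf <- function(texts, ngram_range = c(1L, 2L), min_df = 2L, lowercase = TRUE) {
  if (length(texts) < 2L) stop("need at least 2 documents to fit a featurizer")
  if (ngram_range[1] > ngram_range[2] || ngram_range[1] < 1L) {
    stop("invalid ngram_range")
  }
  if (min_df < 1L) stop("min_df must be >= 1")
  term_lists <- lapply(texts, doc_terms, ngram_range = ngram_range, lowercase = lowercase)
  df_counts <- table(unlist(lapply(term_lists, unique)))
  vocab <- sort(names(df_counts)[df_counts >= min_df])
  if (!length(vocab)) stop("empty vocabulary; lower min_df")
  n_doc <- length(texts)
  idf <- log((1 + n_doc) / (1 + as.numeric(df_counts[vocab]))) + 1
  structure(list(vocab = vocab, idf = idf, ngram_range = ngram_range,
                 min_df = min_df, lowercase = lowercase, n_doc = n_doc),
            class = "tfidf_featurizer")
}

#' Transform documents to TF-IDF feature vectors
#'
#' @param object A fitted `tfidf_featurizer`.
#' @param texts Character vector of documents.
#' @return Dense numeric matrix (documents x vocabulary), l2-normalized rows;
#'   documents with no in-vocabulary term map to the zero vector.
#' @export
transform_tfidf <- function(object, texts) {
  stopifnot(inherits(object, "tfidf_featurizer"))
  V <- length(object$vocab)
  X <- matrix(0, nrow = length(texts), ncol = V,
              dimnames = list(NULL, object$vocab))
  for (i in seq_along(texts)) {
    terms <- doc_terms(texts[i], object$ngram_range, object$lowercase)
    idx <- match(terms, object$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      cnt <- table(idx)
      j <- as.integer(names(cnt))
      v <- as.numeric(cnt) * object$idf[j]
      nrm <- sqrt(sum(v^2))
      X[i, j] <- v / nrm
    }
  }
  X
}
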