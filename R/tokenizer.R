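# Word-level tokenizer for the neural models and the tiny masked LM.
# Four special ids are reserved: <pad> (1), <unk> (2), <mask> (3), <sep> (4);
# vocabulary words start at id 5, ordered by frequency then lexicographically,
# so the vocabulary is deterministic for a given corpus.

PAD_ID <- 1L
UNK_ID <- 2L
MASK_ID <- 3L
SEP_ID <- 4L
N_SPECIALS <- 4L

tokenize_text <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z0-9]+|[[:punct:]]", tolower(text)))[[1]]
}

#' Build a word-level tokenizer
#'
#' Whitespace + punctuation tokenization (lowercased); the vocabulary keeps the
#' `vocab_cap` most frequent tokens (ties broken lexicographically) plus four
#' reserved specials: padding, out-of-vocabulary, mask and separator. Tokens
#' unseen in training map to the OOV id.
#'
#' @param texts Character vector of training texts (non-empty).
#' @param vocab_cap Maximum number of non-special vocabulary entries
#'   (default unlimited).
#' @param extra_texts Optional additional texts whose tokens must be in the
#'   vocabulary (e.g. prompt template and verbalizer phrases).
#' @return An object of class `radr_tokenizer`.
#' @export
build_tokenizer <- function(texts, vocab_cap = Inf, extra_texts = character(0)) {
  if (!length(texts)) stop("empty corpus")
  counts <- table(unlist(lapply(c(texts, extra_texts), tokenize_text)))
  ord <- order(-as.numeric(counts), names(counts), method = "radix")
  words <- names(counts)[ord]
  if (is.finite(vocab_cap)) words <- utils::head(words, vocab_cap)
  vocab <- c("<pad>", "<unk>", "<mask>", "<sep>", words)
  structure(list(vocab = vocab,
                 id = setNames(seq_along(vocab), vocab),
                 vocab_cap = vocab_cap),
            class = "radr_tokenizer")
}

#' Encode a text to token ids
#'
#' @param tokenizer A `radr_tokenizer`.
#' @param text Character scalar.
#' @param max_len Optional truncation length (tail truncated).
#' @return Integer vector of token ids (OOV tokens map to the reserved id).
#' @export
encode_ids <- function(tokenizer, text, max_len = Inf) {
  toks <- tokenize_text(text)
  ids <- unname(tokenizer$id[toks])
  ids[is.na(ids)] <- UNK_ID
  if (is.finite(max_len) && length(ids) > max_len) ids <- ids[seq_len(max_len)]
  as.integer(ids)
}

#' @export
print.radr_tokenizer <- function(x, ...) {
  cat(sprintf("<radr_tokenizer> %d entries (%d specials)\n",
              length(x$vocab), N_SPECIALS))
  invisible(x)
}

vocab_size <- function(tokenizer) length(tokenizer$vocab)
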