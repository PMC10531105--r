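# Sentence handling for conclusion texts. Permutation augmentation operates at
# the sentence level, so segmentation must round-trip: joining the sentences
# with single spaces reproduces the whitespace-normalized input.

normalize_ws <- function(x) gsub("\\s+", " ", trimws(x))

# abbreviations whose trailing period must not end a sentence
.abbrevs <- c("e.g.", "i.e.", "cf.", "approx.", "vs.", "etc.", "no.", "fig.", "dr.")

#' Split a conclusion text into sentences
#'
#' Splits at sentence-final punctuation (. ! ?) followed by whitespace, while
#' protecting common abbreviations ("e.g.", "approx.", ...) and numbered-list
#' markers ("1.", "2."). The concatenation of the returned sentences with a
#' single separating space equals the whitespace-normalized input, so
#' sentence-permuted variants preserve the token multiset exactly.
#'
#' @param text A non-empty character scalar.
#' @return Character vector of sentences (length 1 if no boundary is found).
#' @export
split_sentences <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("text must be a non-empty string")
  }
  s <- normalize_ws(text)
  guard <- "\u2024"  # placeholder for protected periods
  for (ab in .abbrevs) {
    pat <- paste0("(?i)(?<![a-z])", gsub("\\.", "\\\\.", ab))
    repl <- gsub(".", guard, ab, fixed = TRUE)
    s <- gsub(pat, repl, s, perl = TRUE)
  }
  # numbered-list markers: a short integer followed by ". " (e.g. "1. Stable")
  s <- gsub("(?<=\\b[0-9])\\.(?=\\s)", guard, s, perl = TRUE)
  parts <- strsplit(s, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  gsub(guard, ".", parts, fixed = TRUE)
}

join_sentences <- function(sentences) paste(sentences, collapse = " ")
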