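# Shared fixtures, generated in code and cached for the session.

# default synthetic corpus (80 patients) with splits assigned
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_corpus(80, seed = 11)
      cache <<- split_by_patient(co, seed = 1)
    }
    cache
  }
})

# four disjoint class vocabularies: a unigram rule suffices to classify
separable_corpus <- function(n, offset = 0, seed = 1) {
  vocab <- list(NED = c("clearance", "resolution", "negative"),
                PR = c("regression", "reduction", "shrinkage"),
                SD = c("plateau", "unchanged", "steady"),
                PD = c("expansion", "progression", "worsening"))
  set.seed(seed + offset)
  lab <- sample(names(vocab), n, replace = TRUE)
  txt <- vapply(seq_len(n), function(i) {
    w <- sample(vocab[[lab[i]]], 3, replace = TRUE)
    paste0(paste(w, collapse = " "), ". Findings reviewed.")
  }, character(1))
  corpus(paste0("r", offset + seq_len(n)), paste0("p", offset + seq_len(n)),
         txt, lab)
}

# a conclusion text with n distinct sentences
n_sentence_text <- function(n) {
  paste(sprintf("Sentence number %s is here.",
                c("one", "two", "three", "four", "five", "six", "seven")[seq_len(n)]),
        collapse = " ")
}

tiny_tf_spec <- function() {
  encoder_spec("tiny_transformer", embedding_dim = 16L, n_layers = 1L,
               n_heads = 2L, ff_dim = 32L, max_seq_len = 48L)
}
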