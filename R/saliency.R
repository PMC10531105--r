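# Token saliency: which words drove a prediction. For transformer models the
# default recipe is the mean over heads of the final layer's attention from
# the classification (CLS) position; gradient x input is available for every
# architecture as an alternative.

#' Per-token saliency weights for a prediction
#'
#' `method = "attention"` (transformer only): mean over heads of the final
#' encoder layer's attention from the classification position to each token,
#' min-max normalized to \[0, 1\]. `method = "grad_input"` (any architecture):
#' l2 norm of the gradient of the predicted-class logit with respect to each
#' token's input embedding, min-max normalized. A single-token input gets
#' weight 1.
#'
#' @param model A `neural_classifier`.
#' @param text Conclusion text (character scalar).
#' @param method "attention" or "grad_input".
#' @return List with `tokens` (character) and `weights` (numeric in \[0, 1\]).
#' @export
saliency <- function(model, text, method = c("attention", "grad_input")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "neural_classifier"))
  toks <- tokenize_text(text)
  ids <- encode_ids(model$tokenizer, text, model$spec$max_seq_len)
  toks <- toks[seq_along(ids)]
  fo <- classifier_fwd(model$params, model$spec, ids, text)
  if (method == "attention") {
    if (model$spec$kind != "tiny_transformer") {
      stop("attention saliency requires a transformer model; use method = \"grad_input\"")
    }
    last <- fo$cache$fwd$caches[[length(fo$cache$fwd$caches)]]
    M <- matrix(unlist(lapply(last$at$A, function(A) A[1L, -1L])),
                nrow = length(ids))
    w <- rowMeans(M)
  } else {
    if (model$spec$kind == "pretrained_adapter") {
      stop("grad_input saliency requires access to token embeddings")
    }
    cls <- which.max(fo$p)
    dlog <- numeric(4)
    dlog[cls] <- 1
    g <- classifier_bwd(model$params, model$spec, fo$cache, dlog)
    dX <- attr(g, "dXpos")
    w <- sqrt(rowSums(dX^2))
  }
  rng <- range(w)
  weights <- if (diff(rng) < 1e-12) rep(1, length(w)) else (w - rng[1]) / diff(rng)
  list(tokens = toks, weights = weights)
}

#' Render saliency weights as shaded HTML
#'
#' Each token is wrapped in a span whose red background intensity is
#' proportional to its weight (the usual attention-heatmap rendering of
#' clinical NLP papers).
#'
#' @param sal Output of [saliency()] (or a list with `tokens` and `weights`).
#' @return A character scalar of HTML.
#' @export
render_saliency <- function(sal) {
  stopifnot(length(sal$tokens) == length(sal$weights))
  spans <- vapply(seq_along(sal$tokens), function(i) {
    sprintf('<span style="background-color: rgba(255,0,0,%.3f)">%s</span>',
            0.85 * sal$weights[i], sal$tokens[i])
  }, character(1))
  paste0("<div>", paste(spans, collapse = " "), "</div>")
}
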