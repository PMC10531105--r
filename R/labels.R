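#' Disease response labels
#'
#' The four-class response vocabulary used throughout the package, in fixed
#' code order: NED (0, no evidence of disease), PR (1, partial response),
#' SD (2, stable disease), PD (3, progressive disease). The integer codes are
#' the keys of the default prompt verbalizer.
#'
#' @return Character vector `c("NED", "PR", "SD", "PD")`.
#' @export
response_levels <- function() c("NED", "PR", "SD", "PD")

#' Convert a response label name to its integer code
#'
#' @param name Character vector of label names (case-insensitive).
#' @return Integer vector of codes in 0..3.
#' @export
label_code <- function(name) {
  idx <- match(toupper(as.character(name)), response_levels())
  if (anyNA(idx)) {
    bad <- unique(name[is.na(idx)])
    stop("unknown response label(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' Convert an integer response code to its label name
#'
#' @param code Integer vector of codes in 0..3.
#' @return Character vector of label names.
#' @export
label_name <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 3L)) {
    stop("response codes must be integers in 0..3")
  }
  response_levels()[code + 1L]
}

#' Canonicalize a response label
#'
#' Accepts label names (any case) or integer codes 0..3 (also as strings, for
#' interoperability with the verbalizer keys) and returns canonical names.
#'
#' @param x Vector of labels as names or codes.
#' @return Character vector of canonical label names.
#' @export
as_response_label <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  is_code <- grepl("^[0-3]$", x)
  out[is_code] <- label_name(as.integer(x[is_code]))
  if (any(!is_code)) out[!is_code] <- response_levels()[label_code(x[!is_code]) + 1L]
  out
}

# argmax over the 4 classes with lowest-code tie-break; p is a matrix or vector
argmax_label <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  response_levels()[max.col(p, ties.method = "first")]
}
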