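#' Construct a labeled report corpus
#'
#' A corpus is a data frame (class `"response_corpus"`) of radiology report
#' records. Each record carries a unique `report_id`, a `patient_id` (several
#' reports may share one patient), the free-text `conclusion_text` (the summary
#' section of the report, the sole model input), a four-class response `label`,
#' a `split` tag and a `provenance` tag.
#'
#' @param report_id Character vector of unique report identifiers.
#' @param patient_id Character vector of patient identifiers.
#' @param conclusion_text Character vector of conclusion texts (non-empty).
#' @param label Labels as names (NED/PR/SD/PD, any case) or codes 0..3.
#' @param split Split tags, each one of train/dev/test/unassigned.
#' @param provenance Either "synthetic" or "external".
#' @param roles Optional list of character vectors: the sentence-role multiset
#'   of each record (kept by the synthetic generator for oracle audits).
#' @return A `response_corpus` data frame.
#' @export
corpus <- function(report_id, patient_id, conclusion_text, label,
                   split = "unassigned", provenance = "external", roles = NULL) {
  df <- data.frame(
    report_id = as.character(report_id),
    patient_id = as.character(patient_id),
    conclusion_text = as.character(conclusion_text),
    label = as_response_label(label),
    split = rep_len(as.character(split), length(report_id)),
    provenance = rep_len(as.character(provenance), length(report_id)),
    stringsAsFactors = FALSE
  )
  if (!is.null(roles)) df$roles <- I(roles)
  validate_corpus(df)
}

validate_corpus <- function(df) {
  req <- c("report_id", "patient_id", "conclusion_text", "label", "split", "provenance")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("corpus is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    norm <- normalize_ws(df$conclusion_text)
    if (any(!nzchar(norm))) {
      stop("empty conclusion_text for report(s): ",
           paste(df$report_id[!nzchar(norm)], collapse = ", "))
    }
    dup <- df$report_id[duplicated(df$report_id)]
    if (length(dup)) stop("duplicate report_id: ", paste(unique(dup), collapse = ", "))
    df$label <- as_response_label(df$label)
    ok_split <- df$split %in% c("train", "dev", "test", "unassigned")
    if (any(!ok_split)) stop("invalid split tag(s): ",
                             paste(unique(df$split[!ok_split]), collapse = ", "))
    if (any(!df$provenance %in% c("synthetic", "external"))) {
      stop("provenance must be 'synthetic' or 'external'")
    }
    by_pat <- split(df$split, df$patient_id)
    bad <- names(by_pat)[vapply(by_pat, function(s) {
      s <- setdiff(unique(s), "unassigned"); length(s) > 1L
    }, logical(1))]
    if (length(bad)) stop("patient(s) span multiple splits: ", paste(bad, collapse = ", "))
  }
  class(df) <- unique(c("response_corpus", class(df)))
  df
}

#' @export
print.response_corpus <- function(x, ...) {
  cat(sprintf("<response_corpus> %d reports, %d patients\n",
              nrow(x), length(unique(x$patient_id))))
  if (nrow(x)) {
    tab <- table(factor(x$label, levels = response_levels()))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    st <- table(factor(x$split, levels = c("train", "dev", "test", "unassigned")))
    cat("  splits:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.response_corpus <- function(object, ...) {
  print(object)
  if (nrow(object)) print(class_distribution(object))
  invisible(object)
}

#' Read a corpus from a JSON-lines file
#'
#' One JSON object per line with required keys `report_id`, `patient_id`,
#' `conclusion_text`, `label` and optional `split`, `provenance`, `roles`.
#' Labels are parsed case-insensitively; integer codes 0..3 are accepted.
#' Malformed lines are reported with their line numbers.
#'
#' @param path Path to a JSON-lines corpus file.
#' @return A `response_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines_keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(lines_keep))
  errs <- character(0)
  req <- c("report_id", "patient_id", "conclusion_text", "label")
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    obj <- tryCatch(jsonlite::fromJSON(lines[ln]), error = function(e) e)
    if (inherits(obj, "error")) {
      errs <- c(errs, sprintf("line %d: invalid JSON (%s)", ln, conditionMessage(obj)))
      next
    }
    miss <- req[!req %in% names(obj)]
    if (length(miss)) {
      errs <- c(errs, sprintf("line %d: missing required field(s): %s",
                              ln, paste(miss, collapse = ", ")))
      next
    }
    recs[[i]] <- list(
      report_id = as.character(obj$report_id),
      patient_id = as.character(obj$patient_id),
      conclusion_text = as.character(obj$conclusion_text),
      label = as_response_label(obj$label),
      split = if (is.null(obj$split)) "unassigned" else as.character(obj$split),
      provenance = if (is.null(obj$provenance)) "external" else as.character(obj$provenance),
      roles = if (is.null(obj$roles)) NULL else as.character(obj$roles)
    )
  }
  if (length(errs)) stop("corpus parse error(s):\n", paste(errs, collapse = "\n"))
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    return(corpus(character(0), character(0), character(0), character(0)))
  }
  has_roles <- any(vapply(recs, function(r) !is.null(r$roles), logical(1)))
  df <- data.frame(
    report_id = vapply(recs, `[[`, "", "report_id"),
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    conclusion_text = vapply(recs, `[[`, "", "conclusion_text"),
    label = vapply(recs, `[[`, "", "label"),
    split = vapply(recs, `[[`, "", "split"),
    provenance = vapply(recs, `[[`, "", "provenance"),
    stringsAsFactors = FALSE
  )
  if (has_roles) {
    df$roles <- I(lapply(recs, function(r) if (is.null(r$roles)) character(0) else r$roles))
  }
  validate_corpus(df)
}

#' Write a corpus to a JSON-lines file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces all
#' record fields. Labels are serialized by name.
#'
#' @param x A `response_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(x, path) {
  x <- validate_corpus(x)
  lines <- vapply(seq_len(nrow(x)), function(i) {
    obj <- list(
      report_id = x$report_id[i],
      patient_id = x$patient_id[i],
      conclusion_text = x$conclusion_text[i],
      label = x$label[i],
      split = x$split[i],
      provenance = x$provenance[i]
    )
    if (!is.null(x$roles)) obj$roles <- x$roles[[i]]
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Largest-remainder apportionment of n units over fractions; ties broken by
# earlier index. Always sums to n.
apportion <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, seq_along(fractions), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign train/dev/test splits at the patient level
#'
#' All reports of one patient land in a single split, so that models are always
#' evaluated on unseen patients (no leakage through prior reports). The sorted
#' patient list is shuffled with the seeded generator and cut; patient counts
#' per split follow largest-remainder apportionment of the fractions, so 10
#' patients at (0.8, 0.1, 0.1) give exactly 8/1/1.
#'
#' @param x A `response_corpus`.
#' @param fractions Numeric length-3 vector (train, dev, test), each in (0,1),
#'   summing to 1.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return The corpus with its `split` column filled in.
#' @export
split_by_patient <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  x <- validate_corpus(x)
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stop("fractions must be three values in (0,1)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  patients <- sort(unique(x$patient_id))
  if (length(patients) < 3L) stop("need at least 3 patients to form 3 splits")
  set.seed(as.integer(seed))
  shuffled <- sample(patients)
  counts <- apportion(length(patients), fractions)
  tags <- rep(c("train", "dev", "test"), counts)
  assignment <- setNames(tags, shuffled)
  x$split <- unname(assignment[x$patient_id])
  validate_corpus(x)
}

#' Class distribution per split
#'
#' Counts and percentages of each response label, per split and in total,
#' mirroring the usual dataset-characteristics table of report-classification
#' studies. Percentages are within-split, rounded to 1 decimal place.
#'
#' @param x A `response_corpus` (non-empty).
#' @return Data frame with columns `split`, `label`, `count`, `percent`.
#' @export
class_distribution <- function(x) {
  x <- validate_corpus(x)
  if (!nrow(x)) stop("empty corpus")
  splits_present <- intersect(c("train", "dev", "test", "unassigned"), unique(x$split))
  blocks <- lapply(c(splits_present, "total"), function(s) {
    sub <- if (s == "total") x else x[x$split == s, , drop = FALSE]
    cnt <- as.integer(table(factor(sub$label, levels = response_levels())))
    data.frame(split = s, label = response_levels(), count = cnt,
               percent = round(100 * cnt / nrow(sub), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}
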