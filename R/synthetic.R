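# Synthetic radiology-conclusion generator.
#
# Emulates the statistical structure the downstream methods rely on: multi-
# sentence conclusions whose sentences are order-exchangeable, ~6 reports per
# patient, four-class marginals matching the reference study population
# (39.0/11.4/14.4/35.2 percent for NED/PR/SD/PD), class-determining lexical
# cues, and label-neutral distractor sentences. Each record's label is, by
# construction, the output of a rule-based oracle on the multiset of sentence
# roles, so labels are permutation-invariant and auditable.

.role_vocab <- c("ned_statement", "shrink", "stable", "growth", "new_lesion",
                 "benign", "distractor")

.sites <- c("liver", "right lower lobe of the lung", "left kidney", "pancreas",
            "pelvis", "mediastinum", "para-aortic region", "spleen",
            "right adrenal gland", "peritoneum", "left iliac chain", "omentum")

.lesions <- c("nodule", "mass", "lesion", "lymph node", "metastatic deposit",
              "hypodense lesion", "soft tissue density")

.templates <- list(
  ned_statement = c(
    "No evidence of residual or recurrent disease in the {site}.",
    "No suspicious {lesion} is identified.",
    "No evidence of local recurrence or distant metastasis.",
    "Complete resolution of the previously seen {site} {lesion}.",
    "No new or enlarging {lesion} to suggest active disease.",
    "Post-treatment changes in the {site} without evidence of disease.",
    "The previously noted {site} {lesion} is no longer seen.",
    "No abnormal enhancement to indicate viable tumour."
  ),
  shrink = c(
    "Interval decrease in size of the {site} {lesion}, now {size1} cm from {size2} cm.",
    "The {site} {lesion} has decreased from {size2} cm to {size1} cm.",
    "Partial regression of the {site} {lesion}, currently {size1} cm versus {size2} cm previously.",
    "Reduction in size of the dominant {site} {lesion}, measuring {size1} cm compared with {size2} cm.",
    "The {lesion} in the {site} is smaller, {size1} cm from {size2} cm on the prior study.",
    "Interval regression of the {site} {lesion} burden, index {lesion} now {size1} cm from {size2} cm.",
    "Marked shrinkage of the {site} {lesion} since the prior scan, {size1} cm versus {size2} cm.",
    "The treated {site} {lesion} shows interval decrease, {size1} cm from {size2} cm."
  ),
  stable = c(
    "Stable {site} {lesion} measuring {size1} cm, unchanged from {size2} cm.",
    "The {site} {lesion} is unchanged at {size1} cm.",
    "No significant interval change in the {site} {lesion}, again {size1} cm.",
    "Stable appearance of the {site} {lesion} compared with the prior study.",
    "The {lesion} in the {site} remains stable at {size1} cm.",
    "Unchanged {site} {lesion}, {size1} cm, similar to the previous examination.",
    "Stable disease burden in the {site}, index {lesion} {size1} cm.",
    "The known {site} {lesion} shows no interval change, measuring {size1} cm."
  ),
  growth = c(
    "Interval increase in size of the {site} {lesion}, now {size1} cm from {size2} cm.",
    "The {site} {lesion} has enlarged from {size2} cm to {size1} cm.",
    "Progression of the {site} {lesion}, currently {size1} cm versus {size2} cm previously.",
    "Increase in size of the dominant {site} {lesion}, measuring {size1} cm compared with {size2} cm.",
    "The {lesion} in the {site} is larger, {size1} cm from {size2} cm on the prior study.",
    "Worsening {site} {lesion} burden, index {lesion} now {size1} cm from {size2} cm.",
    "Interval enlargement of the {site} {lesion}, {size1} cm versus {size2} cm.",
    "The known {site} {lesion} has grown, now measuring {size1} cm from {size2} cm."
  ),
  new_lesion = c(
    "New {lesion} in the {site} measuring {size1} cm.",
    "Interval development of a {size1} cm {lesion} in the {site}.",
    "A new {size1} cm {lesion} has appeared in the {site}.",
    "Newly identified {site} {lesion}, {size1} cm, not present previously.",
    "New focus of disease in the {site}, a {size1} cm {lesion}.",
    "Interval appearance of a suspicious {lesion} in the {site}, {size1} cm.",
    "There is a new {lesion} within the {site} measuring {size1} cm.",
    "New metastatic focus in the {site}, approx. {size1} cm."
  ),
  benign = c(
    "Simple cyst in the {site}, unchanged.",
    "Degenerative changes of the thoracolumbar spine.",
    "Atherosclerotic calcification of the abdominal aorta.",
    "Small hiatal hernia, incidental.",
    "Benign-appearing {site} cyst, stable.",
    "Cholelithiasis without cholecystitis.",
    "Diverticulosis of the sigmoid colon without diverticulitis.",
    "Renal cortical cyst, simple, requiring no follow-up."
  ),
  distractor = c(
    "No pleural effusion or pneumothorax.",
    "The visualized bowel loops are unremarkable.",
    "No free fluid or free gas in the abdomen.",
    "The adrenal glands are unremarkable.",
    "No hydronephrosis bilaterally.",
    "Central airways are patent.",
    "No acute bony abnormality.",
    "The urinary bladder is unremarkable.",
    "Mild dependent atelectasis at both lung bases.",
    "No significant mediastinal shift."
  ),
  hedge = c(
    "Subcentimeter {site} {lesion}, likely benign.",
    "Tiny {site} {lesion}, too small to characterize, statistically benign.",
    "Ill-defined density in the {site}, suspicious for infection rather than malignancy.",
    "Borderline prominent {site} {lesion}, of uncertain significance.",
    "Possible {lesion} in the {site}, cf. prior imaging; likely artefactual.",
    "Equivocal focus in the {site}, attention on follow-up.",
    "Likely post-treatment change in the {site}, e.g. fibrosis.",
    "Indeterminate tiny {site} {lesion}, probably of no clinical significance."
  )
)

#' Rule-based label oracle for a sentence-role multiset
#'
#' Stands in for the consensus annotation guidelines of a human curation team:
#' any growth or new lesion dominates (PD); otherwise any shrinking lesion
#' (PR); otherwise any stable lesion (SD); otherwise NED. The rule depends only
#' on the multiset of roles, so it is invariant to sentence order by
#' construction.
#'
#' @param roles Character vector of sentence roles (may be empty).
#' @return A response label name.
#' @export
oracle_label <- function(roles) {
  roles <- as.character(roles)
  bad <- setdiff(roles, .role_vocab)
  if (length(bad)) stop("unknown sentence role(s): ", paste(unique(bad), collapse = ", "))
  if (any(roles %in% c("growth", "new_lesion"))) return("PD")
  if (any(roles == "shrink")) return("PR")
  if (any(roles == "stable")) return("SD")
  "NED"
}

render_sentence <- function(role, template) {
  site <- sample(.sites, 1L)
  lesion <- sample(.lesions, 1L)
  s2 <- round(runif(1, 0.8, 5.0), 1)
  s1 <- switch(role,
               shrink = round(s2 * runif(1, 0.3, 0.8), 1),
               growth = round(s2 * runif(1, 1.3, 2.0), 1),
               stable = s2,
               round(runif(1, 0.5, 3.0), 1))
  out <- gsub("{site}", site, template, fixed = TRUE)
  out <- gsub("{lesion}", lesion, out, fixed = TRUE)
  out <- gsub("{size1}", format(s1, nsmall = 1), out, fixed = TRUE)
  gsub("{size2}", format(s2, nsmall = 1), out, fixed = TRUE)
}

# Compose a role multiset consistent with a target label. The defining role
# appears 1 + Binomial(2, 0.5) times, keeping single-sentence conclusions rare
# (so permutation augmentation is almost always exercised).
compose_roles <- function(label, distractor_range) {
  n_core <- 1L + rbinom(1L, 2L, 0.5)
  core <- switch(label,
    NED = rep("ned_statement", n_core),
    PR  = rep("shrink", n_core),
    SD  = rep("stable", n_core),
    PD  = sample(c("growth", "new_lesion"), n_core, replace = TRUE)
  )
  extras <- character(0)
  if (label == "PD") {
    if (runif(1) < 0.3) extras <- c(extras, "stable")
    if (runif(1) < 0.15) extras <- c(extras, "shrink")   # mixed response
  }
  if (label == "PR" && runif(1) < 0.3) extras <- c(extras, "stable")
  if (runif(1) < 0.35) extras <- c(extras, "benign")
  n_d <- sample(seq(distractor_range[1], distractor_range[2]), 1L)
  c(core, extras, rep("distractor", n_d))
}

#' Generate a synthetic labeled report corpus
#'
#' Patients receive `1 + Poisson(mean_reports_per_patient - 1)` reports each.
#' For every report a target label is sampled from `class_marginals`, a role
#' multiset consistent with that label is composed (defining cues, optional
#' label-compatible secondary findings, benign incidentals, 0-3 distractors and
#' an optional hedging sentence), one template per role instance is filled with
#' site/lesion/size slots, and the sentences are shuffled. The stored label
#' always equals `oracle_label()` of the role multiset.
#'
#' @param n_patients Number of patients (>= 1).
#' @param mean_reports_per_patient Mean reports per patient (default 6).
#' @param class_marginals Probability 4-vector over NED/PR/SD/PD (default
#'   `c(0.390, 0.114, 0.144, 0.352)`, the reference population distribution).
#' @param distractor_range Integer interval for distractor counts (default
#'   `c(0, 3)`).
#' @param hedging_prob Probability of adding one label-neutral hedging sentence
#'   (default 0.1).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return A `response_corpus` with `provenance = "synthetic"` and a `roles`
#'   list-column recording each record's role multiset.
#' @export
generate_corpus <- function(n_patients,
                            mean_reports_per_patient = 6,
                            class_marginals = c(0.390, 0.114, 0.144, 0.352),
                            distractor_range = c(0L, 3L),
                            hedging_prob = 0.1,
                            seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (mean_reports_per_patient < 1) stop("mean_reports_per_patient must be >= 1")
  if (length(class_marginals) != 4L || any(class_marginals < 0) ||
      abs(sum(class_marginals) - 1) > 1e-6) {
    stop("class_marginals must be a probability 4-vector")
  }
  if (hedging_prob < 0 || hedging_prob > 1) stop("hedging_prob must be in [0,1]")
  set.seed(as.integer(seed))
  rows <- list()
  roles_col <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%05d", p)
    n_rep <- 1L + stats::rpois(1L, mean_reports_per_patient - 1)
    for (r in seq_len(n_rep)) {
      lab <- sample(response_levels(), 1L, prob = class_marginals)
      roles <- compose_roles(lab, distractor_range)
      sents <- vapply(roles, function(role) {
        render_sentence(role, sample(.templates[[role]], 1L))
      }, character(1), USE.NAMES = FALSE)
      if (runif(1) < hedging_prob) {
        roles <- c(roles, "distractor")
        sents <- c(sents, render_sentence("distractor", sample(.templates$hedge, 1L)))
      }
      ord <- sample(length(sents))
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = sprintf("%s-R%02d", pid, r),
        patient_id = pid,
        conclusion_text = join_sentences(sents[ord]),
        label = oracle_label(roles),
        split = "unassigned",
        provenance = "synthetic",
        stringsAsFactors = FALSE
      )
      roles_col[[length(roles_col) + 1L]] <- roles[ord]
    }
  }
  df <- do.call(rbind, rows)
  df$roles <- I(roles_col)
  validate_corpus(df)
}

#' Perturb gold labels with an annotation-noise model
#'
#' Emulates a second, imperfect annotator for exercising agreement statistics:
#' each label is, with probability `flip_prob`, resampled from the
#' corresponding row of a 4x4 row-stochastic confusion matrix (rows indexed by
#' the gold label in code order). With `flip_prob = 0` the two label lists are
#' identical and Cohen's kappa is 1.
#'
#' @param x A `response_corpus` or a character vector of gold labels.
#' @param flip_prob Probability of perturbing each label.
#' @param confusion 4x4 row-stochastic matrix (default: uniform rows).
#' @param seed Integer seed.
#' @return List with character vectors `gold` and `noisy`.
#' @export
inject_annotation_noise <- function(x, flip_prob,
                                    confusion = matrix(0.25, 4, 4),
                                    seed = 1L) {
  gold <- if (inherits(x, "response_corpus")) x$label else as_response_label(x)
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0,1]")
  if (!is.matrix(confusion) || any(dim(confusion) != 4L) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion must be a 4x4 row-stochastic matrix")
  }
  set.seed(as.integer(seed))
  noisy <- gold
  flip <- stats::runif(length(gold)) < flip_prob
  for (i in which(flip)) {
    row <- confusion[label_code(gold[i]) + 1L, ]
    noisy[i] <- sample(response_levels(), 1L, prob = row)
  }
  list(gold = gold, noisy = noisy)
}
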