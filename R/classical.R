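# Classical baselines: TF-IDF features with a linear max-margin classifier
# (one-vs-rest SVMs with Platt-calibrated probabilities), multinomial logistic
# regression, gradient-boosted trees, and a soft-voting ensemble of the three.

#' Fit a classical text classifier
#'
#' Fits a TF-IDF featurizer on the supplied records and one of four model
#' kinds:
#' \describe{
#'   \item{`"svm"`}{linear max-margin classifier: one-vs-rest linear SVMs with
#'     per-class sigmoid (Platt) calibration fitted on out-of-fold decision
#'     values from a seeded 3-fold refit, probabilities normalized over
#'     classes.}
#'   \item{`"logreg"`}{multinomial ridge logistic regression (glmnet, fixed
#'     small penalty).}
#'   \item{`"gbt"`}{gradient-boosted trees (xgboost softprob; 200 rounds,
#'     depth 6, learning rate 0.1, single thread).}
#'   \item{`"ensemble"`}{soft-voting ensemble: unweighted mean of the three
#'     members' probability vectors.}
#' }
#' All kinds are deterministic given `seed` and expose probabilities over the
#' four response classes. Argmax ties break toward the lowest class code.
#'
#' @param x A `response_corpus` (typically its training split) or a character
#'   vector of texts (then `labels` is required).
#' @param kind One of "svm", "logreg", "gbt", "ensemble".
#' @param labels Labels, required when `x` is a character vector.
#' @param ngram_range,min_df,lowercase TF-IDF settings, see [fit_tfidf()].
#' @param gbt_nrounds,gbt_depth,gbt_eta Gradient-boosted-tree settings.
#' @param seed Integer seed.
#' @return An object of class `classical_model`.
#' @export
fit_classical <- function(x, kind = c("svm", "logreg", "gbt", "ensemble"),
                          labels = NULL,
                          ngram_range = c(1L, 2L), min_df = 2L, lowercase = TRUE,
                          gbt_nrounds = 200L, gbt_depth = 6L, gbt_eta = 0.1,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (inherits(x, "response_corpus")) {
    texts <- x$conclusion_text
    labels <- x$label
  } else {
    texts <- as.character(x)
    if (is.null(labels)) stop("labels required when x is not a corpus")
    labels <- as_response_label(labels)
  }
  if (length(unique(labels)) < 2L) stop("training set has a single class")
  featurizer <- fit_tfidf(texts, ngram_range, min_df, lowercase)
  X <- transform_tfidf(featurizer, texts)
  fits <- if (kind == "ensemble") {
    list(svm = fit_svm_ovr(X, labels, seed),
         logreg = fit_logreg(X, labels, seed),
         gbt = fit_gbt(X, labels, gbt_nrounds, gbt_depth, gbt_eta, seed))
  } else {
    setNames(list(switch(kind,
      svm = fit_svm_ovr(X, labels, seed),
      logreg = fit_logreg(X, labels, seed),
      gbt = fit_gbt(X, labels, gbt_nrounds, gbt_depth, gbt_eta, seed)
    )), kind)
  }
  structure(list(kind = kind, featurizer = featurizer, fits = fits,
                 classes = response_levels(), seed = seed),
            class = "classical_model")
}

# ---- member fitters ----------------------------------------------------

fit_svm_ovr <- function(X, labels, seed) {
  set.seed(as.integer(seed))
  classes <- intersect(response_levels(), unique(labels))
  n <- nrow(X)
  folds <- sample(rep_len(1:3, n))
  models <- list()
  calib <- list()
  for (cl in classes) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("neg", "pos"))
    full <- e1071::svm(x = X, y = y, kernel = "linear", scale = FALSE, cost = 1)
    # out-of-fold decision values for Platt calibration
    dv <- numeric(n)
    for (f in 1:3) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        m <- full
      } else {
        m <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                        kernel = "linear", scale = FALSE, cost = 1)
      }
      pr <- stats::predict(m, X[!tr, , drop = FALSE], decision.values = TRUE)
      d <- drop(attr(pr, "decision.values"))
      # orient decision values so larger means "pos"
      if (grepl("^neg", colnames(attr(pr, "decision.values"))[1])) d <- -d
      dv[!tr] <- d
    }
    z <- as.numeric(labels == cl)
    sig <- suppressWarnings(stats::glm(z ~ dv, family = stats::binomial()))
    models[[cl]] <- full
    calib[[cl]] <- stats::coef(sig)
  }
  list(type = "svm", classes = classes, models = models, calib = calib)
}

fit_logreg <- function(X, labels, seed) {
  set.seed(as.integer(seed))
  y <- factor(labels, levels = intersect(response_levels(), unique(labels)))
  # small-class warnings are expected in few-shot settings
  fit <- suppressWarnings(
    glmnet::glmnet(Matrix::Matrix(X, sparse = TRUE), y,
                   family = "multinomial", alpha = 0, lambda = 0.01,
                   standardize = FALSE))
  list(type = "logreg", classes = levels(y), fit = fit)
}

fit_gbt <- function(X, labels, nrounds, depth, eta, seed) {
  classes <- intersect(response_levels(), unique(labels))
  y <- match(labels, classes) - 1L
  fit <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = depth, eta = eta, nthread = 1L,
                  seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = nrounds
  )
  list(type = "gbt", classes = classes, fit = fit)
}

# probability matrix (rows = docs, cols = response_levels()) for one member
predict_member <- function(member, X) {
  n <- nrow(X)
  P <- matrix(0, n, 4L, dimnames = list(NULL, response_levels()))
  if (member$type == "svm") {
    raw <- matrix(0, n, length(member$classes))
    for (j in seq_along(member$classes)) {
      cl <- member$classes[j]
      pr <- stats::predict(member$models[[cl]], X, decision.values = TRUE)
      d <- drop(attr(pr, "decision.values"))
      if (grepl("^neg", colnames(attr(pr, "decision.values"))[1])) d <- -d
      b <- member$calib[[cl]]
      raw[, j] <- stats::plogis(b[1] + b[2] * d)
    }
    raw <- raw / pmax(rowSums(raw), 1e-12)
    P[, member$classes] <- raw
  } else if (member$type == "logreg") {
    pr <- stats::predict(member$fit, Matrix::Matrix(X, sparse = TRUE),
                         type = "response")[, , 1]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
    P[, colnames(pr)] <- pr
  } else {
    pr <- stats::predict(member$fit, xgboost::xgb.DMatrix(X, nthread = 1L))
    P[, member$classes] <- pr
  }
  P
}

#' Soft-vote average of member label distributions
#'
#' Unweighted mean of probability matrices (or vectors), renormalized only for
#' numerical safety; the mean of valid distributions is itself valid.
#'
#' @param probs List of probability matrices/vectors of equal shape.
#' @return The averaged probability matrix.
#' @export
soft_vote <- function(probs) {
  if (!length(probs)) stop("empty model list")
  Reduce(`+`, probs) / length(probs)
}

#' Predict from a classical model
#'
#' @param object A `classical_model`.
#' @param newdata A `response_corpus` or character vector of texts.
#' @param type `"prob"` for a probability matrix over NED/PR/SD/PD, `"class"`
#'   for label names (argmax, ties toward the lowest class code).
#' @param ... Unused.
#' @export
predict.classical_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  texts <- if (inherits(newdata, "response_corpus")) newdata$conclusion_text
           else as.character(newdata)
  X <- transform_tfidf(object$featurizer, texts)
  P <- soft_vote(lapply(object$fits, function(m) predict_member(m, X)))
  if (type == "prob") P else argmax_label(P)
}

#' @export
print.classical_model <- function(x, ...) {
  cat(sprintf("<classical_model> kind=%s, vocabulary=%d terms, members: %s\n",
              x$kind, length(x$featurizer$vocab), paste(names(x$fits), collapse = ", ")))
  invisible(x)
}
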