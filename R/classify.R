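#' Linear discriminant analysis with Ledoit-Wolf shrinkage
#'
#' Multiclass LDA with a pooled within-class covariance shrunk toward a
#' scaled identity target.  Shrinkage keeps the discriminant well
#' defined when the feature count approaches or exceeds the sample
#' count, as happens with fine size partitions.  Class priors are equal
#' by default (class sizes here are design artifacts, not prevalences).
#'
#' @param x Numeric matrix, samples by features.
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @param shrinkage `"lw"` for the Ledoit-Wolf closed-form intensity,
#'   `"none"`, or a fixed value in `[0, 1]`.
#' @param priors `"equal"`, `"proportional"`, or a named numeric vector.
#' @return An object of class `evp_lda` with class means, the shrunk
#'   pooled covariance (and its Cholesky factor), priors and the
#'   shrinkage intensity used.
#' @export
fit_lda <- function(x, y, shrinkage = "lw", priors = "equal") {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < 2L)) stop("every class needs at least 2 samples")
  n <- nrow(x); p <- ncol(x); K <- length(classes)
  means <- rowsum(x, y) / as.vector(tab[classes])
  centered <- x - means[y, , drop = FALSE]
  S <- crossprod(centered) / (n - K)
  lambda <- if (identical(shrinkage, "none")) 0
            else if (is.numeric(shrinkage)) shrinkage
            else lw_shrinkage_intensity(centered, S)
  mu_t <- sum(diag(S)) / p
  Ssh <- (1 - lambda) * S + lambda * mu_t * diag(p)
  ch <- tryCatch(chol(Ssh), error = function(e) NULL)
  if (is.null(ch)) {
    if (identical(shrinkage, "none"))
      stop("pooled scatter is singular; use shrinkage")
    Ssh <- Ssh + 1e-8 * mu_t * diag(p)
    ch <- chol(Ssh)
  }
  pr <- if (identical(priors, "equal")) stats::setNames(rep(1 / K, K), classes)
        else if (identical(priors, "proportional"))
          stats::setNames(as.vector(tab[classes]) / n, classes)
        else priors[classes]
  structure(list(classes = classes, means = means, chol = ch,
                 lambda = lambda, priors = pr, p = p),
            class = "evp_lda")
}

# Ledoit-Wolf shrinkage intensity toward the scaled-identity target,
# estimated on within-class-centered rows
lw_shrinkage_intensity <- function(centered, S) {
  n <- nrow(centered); p <- ncol(S)
  mu_t <- sum(diag(S)) / p
  d2 <- sum((S - mu_t * diag(p))^2)
  if (d2 <= 0) return(0)
  xs <- rowSums(centered^2)
  cross <- rowSums((centered %*% S) * centered)
  b2 <- (sum(xs^2) - 2 * sum(cross) + n * sum(S^2)) / n^2
  max(0, min(1, b2 / d2))
}

#' @export
print.evp_lda <- function(x, ...) {
  cat(sprintf("LDA model: %d classes, %d features, shrinkage %.3f\n",
              length(x$classes), x$p, x$lambda))
  invisible(x)
}

#' Predict from a fitted LDA model
#'
#' Discriminant scores are the Gaussian log-densities with shared
#' covariance plus log prior; posteriors are their softmax.  Ties are
#' broken toward the lowest class index.
#'
#' @param object An `evp_lda` model.
#' @param newdata Numeric matrix of samples to classify.
#' @param type `"class"`, `"posterior"`, or `"score"`.
#' @param ... Unused.
#' @return Predicted labels, or a samples-by-classes numeric matrix.
#' @export
predict.evp_lda <- function(object, newdata,
                            type = c("class", "posterior", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  # delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c
  Mi <- backsolve(object$chol,
                  forwardsolve(t(object$chol), t(object$means)))
  lin <- newdata %*% Mi
  const <- -0.5 * colSums(t(object$means) * Mi) + log(object$priors)
  scores <- sweep(lin, 2L, const, "+")
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  if (type == "posterior") {
    m <- apply(scores, 1L, max)
    e <- exp(scores - m)
    return(e / rowSums(e))
  }
  object$classes[apply(scores, 1L, which.max)]
}

#' One-vs-rest ROC AUC
#'
#' For each class, the area under the ROC curve treating that class as
#' positive and all others as negative, computed as the Mann-Whitney
#' concordance of the class's score column (ties count 1/2) via average
#' ranks.
#'
#' @param scores Samples-by-classes numeric matrix with class column
#'   names (posterior probabilities or discriminant scores).
#' @param labels True class labels.
#' @return Named numeric vector of per-class AUCs.
#' @export
roc_auc_ovr <- function(scores, labels) {
  classes <- colnames(scores)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes for ROC")
  vapply(classes, function(cl) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
      stop("class ", cl, " lacks positives or negatives")
    r <- rank(scores[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
}

make_folds <- function(y, k, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Cross-validated LDA classification report
#'
#' Out-of-fold predictions under leave-one-out or seeded stratified
#' k-fold CV, aggregated into the overall accuracy, per-class recall, a
#' probability matrix (row-normalized prediction frequencies per true
#' class) and per-class one-vs-rest AUCs computed from out-of-fold
#' posterior scores.
#'
#' @inheritParams fit_lda
#' @param scheme `"loo"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`; must not exceed the smallest
#'   class size.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `classification_report`: `accuracy`,
#'   `recall`, `probability_matrix`, `auc`, `predictions`, `scheme`,
#'   `seed`.
#' @export
cross_validate <- function(x, y, scheme = c("loo", "kfold"), k = 5,
                           seed = NULL, shrinkage = "lw", priors = "equal") {
  scheme <- match.arg(scheme)
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x)
  fold <- if (scheme == "loo") seq_len(n) else {
    if (k > min(table(y))) stop("k exceeds the smallest class size")
    make_folds(y, k, seed)
  }
  classes <- sort(unique(y))
  post <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(x), classes))
  for (f in unique(fold)) {
    test <- fold == f
    model <- fit_lda(x[!test, , drop = FALSE], y[!test],
                     shrinkage = shrinkage, priors = priors)
    post[test, model$classes] <-
      predict(model, x[test, , drop = FALSE], type = "posterior")
  }
  pred <- classes[apply(post, 1L, which.max)]
  acc <- mean(pred == y)
  prob <- t(vapply(classes, function(cl)
    as.vector(prop.table(table(factor(pred[y == cl], levels = classes)))),
    numeric(length(classes))))
  dimnames(prob) <- list(true = classes, predicted = classes)
  structure(list(accuracy = acc,
                 recall = stats::setNames(diag(prob), classes),
                 probability_matrix = prob,
                 auc = roc_auc_ovr(post, y),
                 predictions = data.frame(truth = y, predicted = pred),
                 scheme = if (scheme == "loo") "leave-one-out"
                          else sprintf("stratified %d-fold", k),
                 seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%s): accuracy %.1f%%\n",
              x$scheme, 100 * x$accuracy))
  cat("Per-class AUC:", paste(sprintf("%s=%.3f", names(x$auc), x$auc),
                              collapse = ", "), "\n")
  invisible(x)
}
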