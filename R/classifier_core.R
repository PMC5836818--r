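#' @importFrom e1071 svm
NULL

# Fit libsvm on an already-standardized feature matrix. Rows must be ordered
# positives first: libsvm assigns the positive decision half-space to the
# first label it encounters, which is how the sign convention (positive score
# = recurrence) is enforced without any post-hoc flipping. Termination
# tolerance 1e-3 (libsvm default): on non-separable label permutations a
# tighter tolerance inflates solve time ~100x while moving weights by < 1e-5.
fit_svm_raw <- function(xs, y, cost) {
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = 1e-3,
                    shrinking = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(xs)
  list(weights = w, bias = -fit$rho)
}

#' Train a linear soft-margin SVM on a gene subset
#'
#' Fits the soft-margin maximum-margin linear classifier (hinge loss with an
#' L2 penalty at the given cost) that separates recurrence from event-free
#' samples based on the expression of the given genes. Features are
#' standardized per gene (z-score) on the training samples, and the learned
#' transform is stored in the classifier so that independent cohorts are
#' scored on exactly the training scale. The sign convention is: a positive
#' weight means higher expression of that gene is associated with higher risk
#' of recurrence (the recurrence class maps to +1).
#'
#' @param x An `expr_matrix` containing (at least) the genes to train on.
#' @param positives Sample ids of the recurrence class.
#' @param negatives Sample ids of the event-free class.
#' @param genes Genes to use; default all features of `x`.
#' @param cost Soft-margin cost parameter (positive); default 1.
#' @param training_cohort Optional cohort name recorded in the classifier.
#' @return An object of class `linear_classifier` with elements `gene_ids`,
#'   `weights` (standardized feature space), `bias`, `center`, `scale`,
#'   `cost`, `training_cohort`. Decision score of a sample is
#'   `sum(weights * (expression - center) / scale) + bias`.
#' @export
train_linear_svm <- function(x, positives, negatives, genes = features_of(x),
                             cost = 1, training_cohort = NA_character_) {
  stopifnot(cost > 0)
  if (length(positives) < 2L || length(negatives) < 2L) {
    stop("need at least 2 samples in each class (got ",
         length(positives), " positive, ", length(negatives), " negative)")
  }
  if (length(intersect(positives, negatives)) > 0L) {
    stop("positives and negatives overlap")
  }
  missing <- setdiff(genes, features_of(x))
  if (length(missing) > 0L) {
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  ids <- c(positives, negatives)
  missing_s <- setdiff(ids, samples_of(x))
  if (length(missing_s) > 0L) {
    stop("samples absent from expression matrix: ",
         paste(missing_s, collapse = ", "))
  }
  feats <- t(x$values[genes, ids, drop = FALSE])
  center <- colMeans(feats)
  scale <- apply(feats, 2L, stats::sd)
  zero_var <- scale == 0 | !is.finite(scale)
  if (any(zero_var)) {
    warning("zero-variance gene(s) in training data, scale set to 1: ",
            paste(genes[zero_var], collapse = ", "))
    scale[zero_var] <- 1
  }
  xs <- sweep(sweep(feats, 2L, center), 2L, scale, "/")
  y <- factor(rep(c("recurrence", "event_free"),
                  c(length(positives), length(negatives))),
              levels = c("recurrence", "event_free"))
  fit <- fit_svm_raw(xs, y, cost)
  structure(list(gene_ids = genes, weights = fit$weights, bias = fit$bias,
                 center = center, scale = scale, cost = cost,
                 training_cohort = training_cohort),
            class = "linear_classifier")
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf("linear_classifier on %d gene(s), cost = %g\n",
              length(x$gene_ids), x$cost))
  print(round(stats::setNames(x$weights, x$gene_ids), 4))
  cat(sprintf("bias: %.4f\n", x$bias))
  invisible(x)
}

#' Decision scores of a classifier on new samples
#'
#' Applies the training-set standardization to the new cohort and returns the
#' signed distance to the separating hyperplane. Higher score means higher
#' predicted risk of recurrence.
#'
#' @param clf A `linear_classifier`.
#' @param x An `expr_matrix` containing all of the classifier's genes.
#' @param samples Sample ids to score; default all samples of `x`.
#' @return Named numeric vector of decision scores.
#' @export
decision_scores <- function(clf, x, samples = samples_of(x)) {
  stopifnot(inherits(clf, "linear_classifier"))
  missing <- setdiff(clf$gene_ids, features_of(x))
  if (length(missing) > 0L) {
    stop("classifier genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  feats <- t(x$values[clf$gene_ids, samples, drop = FALSE])
  xs <- sweep(sweep(feats, 2L, clf$center), 2L, clf$scale, "/")
  drop(xs %*% clf$weights) + clf$bias
}

#' Raw-space weights of a classifier
#'
#' Weights are learned and reported in the standardized feature space; the
#' equivalent raw log2-expression-space weights are `weights / scale` (the
#' centering only shifts the bias). Provided so both scales are available.
#'
#' @param clf A `linear_classifier`.
#' @return Named numeric vector of weights on the raw log2 scale.
#' @export
raw_weights <- function(clf) {
  stats::setNames(clf$weights / clf$scale, clf$gene_ids)
}

#' Serialize a classifier to JSON
#' @param clf A `linear_classifier`.
#' @param path Output path.
#' @export
write_classifier <- function(clf, path) {
  obj <- list(gene_ids = clf$gene_ids, weights = unname(clf$weights),
              bias = clf$bias, center = unname(clf$center),
              scale = unname(clf$scale), cost = clf$cost,
              training_cohort = clf$training_cohort)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a classifier from JSON
#' @param path Path to a JSON file written by [write_classifier()].
#' @return A `linear_classifier`.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    gene_ids = obj$gene_ids,
    weights = stats::setNames(obj$weights, obj$gene_ids),
    bias = obj$bias,
    center = stats::setNames(obj$center, obj$gene_ids),
    scale = stats::setNames(obj$scale, obj$gene_ids),
    cost = obj$cost,
    training_cohort = obj$training_cohort
  ), class = "linear_classifier")
}
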