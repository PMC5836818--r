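#' Conservative Monte Carlo permutation p-value
#'
#' `(r + 1) / (n + 1)` where `r` is the number of permuted statistics at least
#' as large as the observed one; ties count against the observed value. The
#' add-one form is the standard conservative Monte Carlo estimator and never
#' returns zero.
#'
#' @param observed Observed statistic (here: testing-cohort AUC).
#' @param permuted Numeric vector of statistics under permuted labels.
#' @return The p-value estimate.
#' @export
estimate_p <- function(observed, permuted) {
  stopifnot(length(permuted) >= 1L, !anyNA(permuted), !is.na(observed))
  (sum(permuted >= observed) + 1) / (length(permuted) + 1)
}

# Permute a logical label vector: same class counts, uniformly random
# assignment to the fixed samples.
permute_labels <- function(labels) {
  labels[sample.int(length(labels))]
}

#' Permutation significance of a gene subset's testing AUC
#'
#' Estimates the significance of the observed testing-cohort AUC by Monte
#' Carlo label permutation under three strategies:
#'
#' * `train_only`: class labels are permuted within the training cohort, the
#'   classifier is retrained, and the testing AUC is computed against the true
#'   testing labels;
#' * `test_only`: the original classifier is kept and only the testing-cohort
#'   labels are permuted;
#' * `both`: training and testing labels are permuted independently (with
#'   retraining).
#'
#' Permutations shuffle the existing labels (class counts preserved, all
#' permutations equiprobable). Each strategy yields `(r+1)/(n+1)` with `r` the
#' number of permuted testing AUCs at least as large as the observed one; the
#' reported p-value is the maximum (most conservative) of the three. The
#' filtration cascade is not reapplied inside permutations: the permuted
#' testing AUC is computed for every permutation, so the null distribution is
#' not conditioned on filtration survival.
#'
#' @param genes Gene subset (within the meta-set's family).
#' @param meta A `meta_set`.
#' @param n Permutations per strategy (default 10000).
#' @param seed Integer seed; results are bit-identical across reruns with the
#'   same seed.
#' @param cost SVM cost parameter.
#' @param strategies Which strategies to run (default all three).
#' @return An object of class `permutation_result`: list with
#'   `observed_auc`, `n_permutations`, `seed`, `strategy_p` (named numeric)
#'   and `reported_p` (their maximum).
#' @export
permutation_test <- function(genes, meta, n = 10000L, seed = 1L, cost = 1,
                             strategies = c("train_only", "test_only", "both")) {
  stopifnot(n >= 1L)
  strategies <- match.arg(strategies, several.ok = TRUE)
  genes <- sort(genes)
  train_lab <- meta$labelings[[meta$roles$training]]
  test_lab <- meta$labelings[[meta$roles$testing]]
  train_ids <- c(train_lab$positives, train_lab$negatives)
  test_ids <- c(test_lab$positives, test_lab$negatives)
  if (length(test_lab$positives) == 0L || length(test_lab$negatives) == 0L) {
    stop("testing cohort has an empty class")
  }

  clf <- train_linear_svm(meta$expression, train_lab$positives,
                          train_lab$negatives, genes = genes, cost = cost,
                          training_cohort = meta$roles$training)

  # features standardized once with the training transform: label permutation
  # keeps the sample set fixed, so the transform never changes
  feats_train <- t(meta$expression$values[genes, train_ids, drop = FALSE])
  xs_train <- sweep(sweep(feats_train, 2L, clf$center), 2L, clf$scale, "/")
  feats_test <- t(meta$expression$values[genes, test_ids, drop = FALSE])
  xs_test <- sweep(sweep(feats_test, 2L, clf$center), 2L, clf$scale, "/")

  y_train <- rep(c(TRUE, FALSE),
                 c(length(train_lab$positives), length(train_lab$negatives)))
  y_test <- rep(c(TRUE, FALSE),
                c(length(test_lab$positives), length(test_lab$negatives)))

  observed_scores <- drop(xs_test %*% clf$weights) + clf$bias
  observed_auc <- roc_auc(observed_scores, y_test)$auc

  auc_fast <- function(scores, labels) {
    r <- rank(scores)
    n_pos <- sum(labels)
    (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * (length(labels) - n_pos))
  }
  retrain_scores <- function(y_perm) {
    # positives-first row order fixes the sign convention (see fit_svm_raw)
    ord <- order(!y_perm)
    y <- factor(ifelse(y_perm[ord], "recurrence", "event_free"),
                levels = c("recurrence", "event_free"))
    fit <- fit_svm_raw(xs_train[ord, , drop = FALSE], y, cost)
    drop(xs_test %*% fit$weights) + fit$bias
  }

  set.seed(seed)
  strategy_p <- stats::setNames(numeric(length(strategies)), strategies)
  for (s in strategies) {
    permuted <- numeric(n)
    for (i in seq_len(n)) {
      permuted[i] <- switch(
        s,
        train_only = auc_fast(retrain_scores(permute_labels(y_train)), y_test),
        test_only = auc_fast(observed_scores, permute_labels(y_test)),
        both = auc_fast(retrain_scores(permute_labels(y_train)),
                        permute_labels(y_test))
      )
    }
    strategy_p[s] <- estimate_p(observed_auc, permuted)
  }
  structure(list(observed_auc = observed_auc,
                 n_permutations = as.integer(n),
                 seed = as.integer(seed),
                 strategy_p = strategy_p,
                 reported_p = max(strategy_p)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed testing AUC = %.4f (n = %d per strategy)\n",
              x$observed_auc, x$n_permutations))
  for (s in names(x$strategy_p)) {
    cat(sprintf("  %-10s p = %.4g\n", s, x$strategy_p[s]))
  }
  cat(sprintf("  reported (most conservative) p = %.4g\n", x$reported_p))
  invisible(x)
}

#' Serialize a permutation result to JSON
#' @param x A `permutation_result`.
#' @param path Output path.
#' @export
write_permutation_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
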