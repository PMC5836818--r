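#' @importFrom survival Surv survfit survdiff
NULL

#' ROC curve and AUC with midrank tie handling
#'
#' Computes the area under the receiver operating characteristic curve as the
#' probability that a random positive sample outscores a random negative one,
#' with tied scores counting one half (midrank / Mann-Whitney convention). The
#' returned curve is the ROC polygon over the distinct score thresholds,
#' starting at (0,0) and ending at (1,1); its trapezoidal area equals the AUC.
#'
#' @param scores Numeric vector of decision scores.
#' @param labels Logical vector (`TRUE` = positive class), aligned with
#'   `scores`; alternatively a named `scores` vector plus `positives` ids.
#' @param positives Optional character vector of positive sample ids, used
#'   instead of `labels` when `scores` is named.
#' @return An object of class `roc_result`: list with `auc` and `curve`
#'   (data.frame with columns `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels = NULL, positives = NULL) {
  if (is.null(labels)) {
    stopifnot(!is.null(positives), !is.null(names(scores)))
    labels <- names(scores) %in% positives
  }
  stopifnot(length(labels) == length(scores), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be non-empty to compute an ROC curve")
  }
  r <- rank(scores)                      # midranks for ties
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thresholds, function(t) sum(scores[labels] >= t), numeric(1L))
  fp <- vapply(thresholds, function(t) sum(scores[!labels] >= t), numeric(1L))
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

# AUC of a classifier on the classified (positive/negative) samples of one
# cohort of a labeled meta-set.
cohort_auc <- function(clf, meta, cohort) {
  lab <- meta$labelings[[cohort]]
  ids <- c(lab$positives, lab$negatives)
  if (length(lab$positives) == 0L || length(lab$negatives) == 0L) {
    stop("cohort '", cohort, "' has an empty class; cannot compute AUC")
  }
  scores <- decision_scores(clf, meta$expression, ids)
  roc_auc(scores, names(scores) %in% lab$positives)$auc
}

#' Build a filtration verdict from AUC values
#'
#' A classifier passes filtration iff its training AUC is not less than
#' `train_threshold` (default 0.6) and its AUC on every filtration cohort is
#' not less than `filter_threshold` (default 0.55). Boundary equality passes.
#'
#' @param auc_train Training-cohort AUC.
#' @param auc_filters Named numeric vector of filtration-cohort AUCs.
#' @param train_threshold Minimum training AUC.
#' @param filter_threshold Minimum AUC on each filtration cohort.
#' @return An object of class `filtration_verdict`: list with `auc_train`,
#'   `auc_filters`, `passed`, `failed_stage` (`NA` when passed; otherwise
#'   `"training"` or the name of the first failing filtration cohort) and the
#'   two thresholds.
#' @export
filtration_verdict <- function(auc_train, auc_filters,
                               train_threshold = 0.6, filter_threshold = 0.55) {
  stopifnot(length(auc_filters) >= 1L)
  failed_stage <- NA_character_
  if (auc_train < train_threshold) {
    failed_stage <- "training"
  } else {
    below <- which(auc_filters < filter_threshold)
    if (length(below) > 0L) {
      nm <- names(auc_filters)[below[1L]]
      failed_stage <- if (is.null(nm) || is.na(nm)) {
        paste0("filter_", below[1L])
      } else nm
    }
  }
  structure(list(auc_train = auc_train, auc_filters = auc_filters,
                 passed = is.na(failed_stage), failed_stage = failed_stage,
                 train_threshold = train_threshold,
                 filter_threshold = filter_threshold),
            class = "filtration_verdict")
}

#' Apply the AUC filtration cascade to a classifier
#'
#' Computes the classifier's AUC on the training cohort and on each
#' filtration cohort of the meta-set (the training-cohort classifier is
#' applied unchanged, never retrained) and decides pass/fail per
#' [filtration_verdict()]. The testing cohort is not touched.
#'
#' @param clf A `linear_classifier`.
#' @param meta A labeled meta-set (see [meta_set()]).
#' @param train_threshold,filter_threshold See [filtration_verdict()].
#' @return A `filtration_verdict`.
#' @export
apply_filtration <- function(clf, meta, train_threshold = 0.6,
                             filter_threshold = 0.55) {
  auc_train <- cohort_auc(clf, meta, meta$roles$training)
  auc_filters <- vapply(meta$roles$filtration, function(ch) {
    cohort_auc(clf, meta, ch)
  }, numeric(1L))
  names(auc_filters) <- meta$roles$filtration
  filtration_verdict(auc_train, auc_filters, train_threshold, filter_threshold)
}

#' Kaplan-Meier (product-limit) survival curve
#'
#' Product-limit estimate of recurrence-free survival for one group. At tied
#' event/censoring times, events are processed first (the censored sample
#' counts as at risk for that event), the standard convention.
#'
#' @param time Positive times in months.
#' @param event Logical; `TRUE` for an observed event, `FALSE` for censoring.
#' @return An object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, one row per distinct
#'   observed time.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) > 0L, length(time) == length(event))
  if (any(time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Unweighted log-rank chi-square statistic with 1 degree of freedom; the
#' two-sided p-value is the upper tail of the chi-square(1) distribution of
#' the squared standardized statistic (the standard two-sided form for this
#' test). With no events in either group the statistic is 0 and p = 1.
#'
#' @param time Positive times in months (both groups pooled).
#' @param event Logical event indicator.
#' @param group Two-level grouping vector aligned with `time`.
#' @return An object of class `log_rank_result`: list with `statistic` and
#'   `p_two_tailed`.
#' @export
log_rank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("log_rank requires exactly two non-empty groups")
  }
  if (sum(event) == 0L) {
    res <- list(statistic = 0, p_two_tailed = 1)
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    stat <- as.numeric(sd$chisq)
    res <- list(statistic = stat,
                p_two_tailed = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  structure(res, class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4f, two-tailed p = %.4g\n",
              x$statistic, x$p_two_tailed))
  invisible(x)
}

#' Split samples into predicted risk groups by decision score
#'
#' Samples with a decision score strictly above `threshold` (default 0, the
#' classifier's decision boundary) form the predicted high-risk group. If
#' every sample falls on one side a warning is raised and the split is still
#' returned.
#'
#' @param clf A `linear_classifier`.
#' @param x An `expr_matrix`.
#' @param samples Samples to split; default all samples of `x`.
#' @param threshold Score threshold; default 0.
#' @return List with `high_risk`, `low_risk` (character vectors) and `scores`.
#' @export
dichotomize_by_score <- function(clf, x, samples = samples_of(x),
                                 threshold = 0) {
  scores <- decision_scores(clf, x, samples)
  high <- names(scores)[scores > threshold]
  low <- setdiff(names(scores), high)
  if (length(high) == 0L || length(low) == 0L) {
    warning("all samples fall on one side of the score threshold")
  }
  list(high_risk = high, low_risk = low, scores = scores)
}

#' Kaplan-Meier comparison of predicted risk groups on one cohort
#'
#' Dichotomizes the cohort's complete survival population (classified samples
#' plus late events and early-censored samples) by classifier score and runs
#' the two-group log-rank test.
#'
#' @param clf A `linear_classifier`.
#' @param meta A labeled meta-set.
#' @param cohort Cohort name; default the testing cohort.
#' @param threshold Score threshold for the split; default 0.
#' @return List with `log_rank` (a `log_rank_result`), `curves` (named list of
#'   `km_curve` for the high- and low-risk groups) and `groups` (the split).
#' @export
km_comparison <- function(clf, meta, cohort = meta$roles$testing,
                          threshold = 0) {
  km <- km_population(meta$labelings[[cohort]])
  km <- km[km$sample_id %in% samples_of(meta$expression), , drop = FALSE]
  if (nrow(km) == 0L) stop("no survival records for cohort '", cohort, "'")
  risk <- dichotomize_by_score(clf, meta$expression, km$sample_id, threshold)
  grp <- ifelse(km$sample_id %in% risk$high_risk, "high_risk", "low_risk")
  lr <- if (length(unique(grp)) < 2L) {
    # degenerate split: no group comparison possible
    structure(list(statistic = NA_real_, p_two_tailed = NA_real_),
              class = "log_rank_result")
  } else {
    log_rank(km$time, km$event, grp)
  }
  curves <- lapply(split(km, grp), function(d) km_curve(d$time, d$event))
  list(log_rank = lr, curves = curves, groups = risk)
}

#' Write an ROC curve as a TSV coordinate table
#' @param roc A `roc_result`.
#' @param path Output path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(format(roc$curve, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Kaplan-Meier curve as a TSV coordinate table
#' @param curve A `km_curve`.
#' @param path Output path.
#' @export
write_km_tsv <- function(curve, path) {
  utils::write.table(format(as.data.frame(curve), digits = 10, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
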