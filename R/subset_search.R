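#' Enumerate gene subsets of a family
#'
#' All combinations of each requested size, in deterministic lexicographic
#' order (genes sorted, then combinations in lexicographic order), optionally
#' followed by the full family. No duplicates: if the full set is already
#' produced by `sizes`, it is not appended twice.
#'
#' @param genes Character vector, the gene family.
#' @param sizes Integer vector of subset sizes, each in `1..length(genes)`.
#' @param include_full Also evaluate the full family (default `TRUE`).
#' @return List of character vectors (each sorted).
#' @export
enumerate_subsets <- function(genes, sizes = c(1L, 2L, 3L),
                              include_full = TRUE) {
  genes <- sort(unique(genes))
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) > 0L && (min(sizes) < 1L || max(sizes) > length(genes))) {
    stop("subset sizes must lie in 1..", length(genes))
  }
  out <- list()
  for (k in sizes) {
    combos <- utils::combn(genes, k, simplify = FALSE)
    out <- c(out, combos)
  }
  if (include_full && !(length(genes) %in% sizes)) {
    out <- c(out, list(genes))
  }
  out
}

#' Evaluate one gene subset through the train/filter/test cascade
#'
#' Trains a linear soft-margin SVM on the training cohort, applies the AUC
#' filtration cascade (training AUC >= `train_threshold` and every filtration
#' cohort AUC >= `filter_threshold`), and only for classifiers that pass
#' computes the testing-cohort AUC and the Kaplan-Meier log-rank p-value of
#' the score-dichotomized testing cohort. For failed subsets the testing
#' cohort is never read.
#'
#' @param genes Character vector, a subset of the meta-set's gene family.
#' @param meta A `meta_set`.
#' @param cost SVM cost parameter.
#' @param train_threshold,filter_threshold Filtration thresholds.
#' @param km_threshold Score threshold for the risk-group split.
#' @return An object of class `subset_evaluation`: list with `gene_set`
#'   (sorted), `classifier`, `verdict` (a `filtration_verdict`), `auc_test`
#'   (`NA` unless passed), `km_p` (`NA` unless passed).
#' @export
evaluate_subset <- function(genes, meta, cost = 1, train_threshold = 0.6,
                            filter_threshold = 0.55, km_threshold = 0) {
  genes <- sort(genes)
  outside <- setdiff(genes, meta$family)
  if (length(outside) > 0L) {
    stop("subset (", paste(genes, collapse = ","),
         ") contains genes outside the family: ",
         paste(outside, collapse = ", "))
  }
  train_lab <- meta$labelings[[meta$roles$training]]
  clf <- tryCatch(
    train_linear_svm(meta$expression, train_lab$positives,
                     train_lab$negatives, genes = genes, cost = cost,
                     training_cohort = meta$roles$training),
    error = function(e) stop("subset (", paste(genes, collapse = ","), "): ",
                             conditionMessage(e), call. = FALSE))
  verdict <- apply_filtration(clf, meta, train_threshold, filter_threshold)
  auc_test <- NA_real_
  km_p <- NA_real_
  if (verdict$passed) {
    auc_test <- cohort_auc(clf, meta, meta$roles$testing)
    km_p <- suppressWarnings(
      km_comparison(clf, meta, threshold = km_threshold)$log_rank$p_two_tailed)
  }
  structure(list(gene_set = genes, classifier = clf, verdict = verdict,
                 auc_test = auc_test, km_p = km_p),
            class = "subset_evaluation")
}

#' Exhaustive subset search with cross-cohort filtration
#'
#' Runs every enumerated subset of the meta-set's gene family through
#' [evaluate_subset()] and ranks the survivors by descending testing AUC
#' (ties: smaller subset first, then lexicographic gene order). Failed subsets
#' are kept in the report with their stage of failure rather than dropped, so
#' that near-misses are visible.
#'
#' @param meta A `meta_set`.
#' @param sizes Subset sizes to enumerate.
#' @param include_full Also evaluate the full family.
#' @param cost,train_threshold,filter_threshold,km_threshold Passed through.
#' @return An object of class `search_result`: list with `report` (one row
#'   per subset: `gene_set`, `n_genes`, `auc_train`, one `auc_<cohort>` column
#'   per filtration cohort, `passed`, `failed_stage`, `auc_test`, `km_p`,
#'   `weights`) and `evaluations` (list of `subset_evaluation`, same order).
#' @export
run_search <- function(meta, sizes = c(1L, 2L, 3L), include_full = TRUE,
                       cost = 1, train_threshold = 0.6,
                       filter_threshold = 0.55, km_threshold = 0) {
  subsets <- enumerate_subsets(meta$family, sizes, include_full)
  evals <- lapply(subsets, evaluate_subset, meta = meta, cost = cost,
                  train_threshold = train_threshold,
                  filter_threshold = filter_threshold,
                  km_threshold = km_threshold)

  key <- vapply(evals, function(e) paste(e$gene_set, collapse = ","),
                character(1L))
  n_genes <- lengths(subsets)
  auc_test <- vapply(evals, function(e) e$auc_test, numeric(1L))
  passed <- vapply(evals, function(e) e$verdict$passed, logical(1L))
  # survivors by descending testing AUC, then smaller subset, then gene order;
  # failed subsets after all survivors, by size then gene order
  ord <- order(!passed, -ifelse(is.na(auc_test), -Inf, auc_test),
               n_genes, key, method = "radix")
  evals <- evals[ord]

  filters <- meta$roles$filtration
  report <- data.frame(
    gene_set = key[ord],
    n_genes = n_genes[ord],
    auc_train = vapply(evals, function(e) e$verdict$auc_train, numeric(1L)),
    stringsAsFactors = FALSE
  )
  for (ch in filters) {
    report[[paste0("auc_", ch)]] <-
      vapply(evals, function(e) unname(e$verdict$auc_filters[ch]), numeric(1L))
  }
  report$passed <- passed[ord]
  report$failed_stage <-
    vapply(evals, function(e) e$verdict$failed_stage, character(1L))
  report$auc_test <- auc_test[ord]
  report$km_p <- vapply(evals, function(e) e$km_p, numeric(1L))
  report$weights <- vapply(evals, function(e) {
    as.character(jsonlite::toJSON(as.list(round(e$classifier$weights, 6)),
                                  auto_unbox = TRUE))
  }, character(1L))
  structure(list(report = report, evaluations = evals),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  n_pass <- sum(x$report$passed)
  cat(sprintf("search_result: %d subsets evaluated, %d passed filtration\n",
              nrow(x$report), n_pass))
  if (n_pass > 0L) {
    top <- utils::head(x$report[x$report$passed,
                                c("gene_set", "auc_train", "auc_test", "km_p")],
                       5L)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Write a search report as TSV
#' @param res A `search_result`.
#' @param path Output path.
#' @export
write_search_report <- function(res, path) {
  utils::write.table(res$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
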