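#' Assemble a labeled multi-cohort meta-set
#'
#' Bundles a joint expression matrix, per-cohort clinical tables and cohort
#' roles into the object the search and significance machinery operates on.
#' Every cohort is labeled with [label_cohort()] at construction time.
#'
#' @param expression Joint `expr_matrix` spanning all cohorts (gene-level,
#'   after probe collapse and low-expression filtering).
#' @param clinical Named list of clinical data.frames, one per cohort.
#' @param roles List with elements `training` (one cohort name), `filtration`
#'   (one or more cohort names) and `testing` (one cohort name).
#' @param family Character vector: the gene family whose subsets are searched.
#'   Genes absent from `expression` (e.g. removed by the low-expression
#'   filter) are dropped with a message.
#' @param recurrence_window,followup_min,early_exclusion Passed to
#'   [label_cohort()].
#' @return An object of class `meta_set` with elements `expression`,
#'   `clinical`, `labelings`, `roles`, `family`.
#' @export
meta_set <- function(expression, clinical, roles, family,
                     recurrence_window = 36, followup_min = 48,
                     early_exclusion = 1) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (length(roles$training) != 1L || length(roles$testing) != 1L ||
      length(roles$filtration) < 1L) {
    stop("roles must name exactly one training, one testing, and >= 1 filtration cohort")
  }
  all_roles <- c(roles$training, roles$filtration, roles$testing)
  if (anyDuplicated(all_roles)) stop("a cohort cannot hold two roles")
  if (!all(all_roles %in% names(clinical))) {
    stop("clinical tables missing for cohort(s): ",
         paste(setdiff(all_roles, names(clinical)), collapse = ", "))
  }
  if (!all(all_roles %in% unique(expression$cohort))) {
    stop("expression matrix has no samples for cohort(s): ",
         paste(setdiff(all_roles, unique(expression$cohort)), collapse = ", "))
  }
  labelings <- lapply(clinical[all_roles], label_cohort,
                      recurrence_window = recurrence_window,
                      followup_min = followup_min,
                      early_exclusion = early_exclusion)
  for (ch in all_roles) {
    lab <- labelings[[ch]]
    ids <- c(lab$positives, lab$negatives, lab$km$sample_id)
    missing <- setdiff(ids, samples_of(expression))
    if (length(missing) > 0L) {
      stop("cohort '", ch, "': samples without expression data: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  dropped <- setdiff(family, features_of(expression))
  if (length(dropped) > 0L) {
    message("family genes not in the expression matrix (dropped): ",
            paste(dropped, collapse = ", "))
    family <- setdiff(family, dropped)
  }
  if (length(family) == 0L) stop("empty gene family")
  structure(list(expression = expression, clinical = clinical[all_roles],
                 labelings = labelings, roles = roles, family = family),
            class = "meta_set")
}

#' @export
print.meta_set <- function(x, ...) {
  cat(sprintf("meta_set: %d genes (family of %d), cohorts:\n",
              nrow(x$expression$values), length(x$family)))
  role_of <- c(stats::setNames("training", x$roles$training),
               stats::setNames(rep("filtration", length(x$roles$filtration)),
                               x$roles$filtration),
               stats::setNames("testing", x$roles$testing))
  for (ch in names(x$labelings)) {
    lab <- x$labelings[[ch]]
    cat(sprintf("  %s [%s]: %d samples (%d+, %d-)\n", ch, role_of[[ch]],
                lab$n_input, length(lab$positives), length(lab$negatives)))
  }
  invisible(x)
}
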