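#' Construct an expression matrix object
#'
#' Container for a log2 expression matrix (genes or probes in rows, samples in
#' columns) together with a per-sample cohort assignment. All values must be
#' finite; row identifiers must be unique; every sample belongs to exactly one
#' cohort.
#'
#' @param values Numeric matrix with unique rownames (probe or gene
#'   identifiers) and unique colnames (sample identifiers), on the log2 scale.
#' @param cohort Either a single cohort name applied to every sample, or a
#'   named character vector mapping each sample identifier to its cohort.
#' @return An object of class `expr_matrix` with elements `values` (the
#'   matrix) and `cohort` (named character vector, one entry per sample).
#' @export
expression_matrix <- function(values, cohort) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have rownames (features) and colnames (samples)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (length(cohort) == 1L && is.null(names(cohort))) {
    cohort <- stats::setNames(rep(cohort, ncol(values)), colnames(values))
  }
  if (!all(colnames(values) %in% names(cohort))) {
    stop("every sample must have a cohort assignment")
  }
  cohort <- cohort[colnames(values)]
  structure(list(values = values, cohort = cohort), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples; cohorts: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (n=%d)", names(table(x$cohort)),
                            as.integer(table(x$cohort))), collapse = ", ")))
  invisible(x)
}

#' Sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample identifiers.
#' @export
samples_of <- function(x) colnames(x$values)

#' Feature (gene or probe) identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of feature identifiers.
#' @export
features_of <- function(x) rownames(x$values)

strip_quotes <- function(x) gsub('^"|"$', "", x)

parse_expression_lines <- function(lines, cohort, line_offset = 0L) {
  if (length(lines) < 2L) {
    stop("parse error at line ", 1L + line_offset,
         ": empty data section (need a header and at least one data row)")
  }
  header <- strip_quotes(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  if (length(header) < 2L) {
    stop("parse error at line ", 1L + line_offset,
         ": malformed header (need an identifier column and >= 1 sample)")
  }
  sample_ids <- header[-1L]
  n <- length(lines) - 1L
  ids <- character(n)
  vals <- matrix(NA_real_, nrow = n, ncol = length(sample_ids))
  for (i in seq_len(n)) {
    fields <- strip_quotes(strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != length(header)) {
      stop("parse error at line ", i + 1L + line_offset,
           sprintf(": expected %d fields, found %d",
                   length(header), length(fields)))
    }
    ids[i] <- fields[1L]
    row <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop(sprintf(
        "parse error at line %d: non-numeric cell '%s' (feature '%s', sample '%s')",
        i + 1L + line_offset, fields[-1L][j], ids[i], sample_ids[j]))
    }
    vals[i, ] <- row
  }
  dimnames(vals) <- list(ids, sample_ids)
  expression_matrix(vals, cohort)
}

#' Read a log2 expression matrix
#'
#' Reads either a plain tab-separated table (first column probe or gene
#' identifiers, remaining columns samples) or the data section of a GEO Series
#' Matrix file (the table between the `!series_matrix_table_begin` and
#' `!series_matrix_table_end` sentinels; quoted identifiers are tolerated).
#' Values must already be log2-scale normalized; this package does not perform
#' RMA or any other normalization.
#'
#' @param path Path to the file.
#' @param cohort Cohort name to tag every sample with.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, cohort, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin) {
      stop("parse error: series matrix table sentinels not found in ", path)
    }
    if (end - begin < 3L) {
      stop("parse error at line ", begin + 1L, ": empty data section")
    }
    parse_expression_lines(lines[(begin + 1L):(end - 1L)], cohort,
                           line_offset = begin)
  } else {
    parse_expression_lines(lines, cohort)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; numbers are written with six decimal
#' places so that a write/read round trip preserves values.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param id_column Header for the identifier column.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "series_matrix"),
                             id_column = "gene_id") {
  dialect <- match.arg(dialect)
  header <- paste(c(id_column, colnames(x$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i], sprintf("%.6f", x$values[i, ])),
          collapse = "\t")
  }, character(1L))
  body <- c(header, rows)
  if (dialect == "series_matrix") {
    body <- c("!series_matrix_table_begin", body, "!series_matrix_table_end")
  }
  writeLines(body, path)
  invisible(path)
}

#' Combine per-cohort expression matrices into one joint meta-set matrix
#'
#' All matrices must share the same feature set; features are aligned to the
#' order of the first matrix. Sample identifiers must be unique across
#' cohorts.
#'
#' @param ... `expr_matrix` objects (or a single list of them).
#' @return A single `expr_matrix` spanning all cohorts.
#' @export
combine_cohorts <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1L]], "expr_matrix")) ms <- ms[[1L]]
  stopifnot(length(ms) >= 1L)
  feats <- features_of(ms[[1L]])
  for (m in ms) {
    if (!setequal(features_of(m), feats)) {
      stop("cohort matrices do not share the same feature set")
    }
  }
  values <- do.call(cbind, lapply(ms, function(m) m$values[feats, , drop = FALSE]))
  cohort <- do.call(c, lapply(ms, function(m) m$cohort))
  expression_matrix(values, cohort)
}

#' Warn when cohort expression scales look inconsistent
#'
#' A light sanity check on joint preprocessing: computes the median log2
#' expression per cohort and warns when the spread between cohorts exceeds
#' `max_shift` log2 units, which usually indicates the cohorts were not
#' normalized onto a common scale.
#'
#' @param x Joint `expr_matrix`.
#' @param max_shift Maximum tolerated difference between cohort medians
#'   (log2 units).
#' @return Named numeric vector of cohort medians, invisibly.
#' @export
check_cohort_scale <- function(x, max_shift = 2) {
  meds <- vapply(split(seq_len(ncol(x$values)), x$cohort),
                 function(idx) stats::median(x$values[, idx]), numeric(1L))
  if (diff(range(meds)) > max_shift) {
    warning(sprintf(
      "cohort median log2 expression differs by %.2f (> %.1f) units; are all cohorts on one normalized scale?",
      diff(range(meds)), max_shift))
  }
  invisible(meds)
}

#' Read a probe-to-gene annotation table
#'
#' Tab-separated file with columns `probe_id` and `gene_id`.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(tab))) {
    stop("probe annotation must have columns 'probe_id' and 'gene_id'")
  }
  if (anyDuplicated(tab$probe_id)) stop("duplicate probe_id in annotation")
  tab[, c("probe_id", "gene_id")]
}

#' Collapse probe-level rows to one row per gene
#'
#' When an array carries several probes for one gene, only the probe with the
#' highest signal intensity is kept. Intensity is operationalized as the mean
#' log2 signal across all samples of the joint meta-set; ties are broken by
#' the lexicographically smallest probe identifier, so the result is
#' deterministic. The operation is idempotent.
#'
#' @param m Probe-level `expr_matrix` covering the joint meta-set.
#' @param probes Probe annotation data.frame (`probe_id`, `gene_id`), e.g.
#'   from [read_probe_table()].
#' @return Gene-level `expr_matrix` with one row per gene, genes in
#'   lexicographic order.
#' @export
collapse_probes <- function(m, probes) {
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in annotation")
  ids <- features_of(m)
  missing <- setdiff(ids, probes$probe_id)
  if (length(missing) > 0L) {
    stop("probes missing from annotation: ", paste(missing, collapse = ", "))
  }
  gene <- probes$gene_id[match(ids, probes$probe_id)]
  mean_signal <- rowMeans(m$values)
  keep <- vapply(split(seq_along(ids), gene), function(idx) {
    best <- idx[mean_signal[idx] == max(mean_signal[idx])]
    best[order(ids[best])][1L]
  }, integer(1L))
  keep <- keep[order(names(keep))]
  values <- m$values[keep, , drop = FALSE]
  rownames(values) <- names(keep)
  expression_matrix(values, m$cohort)
}

#' Remove stably low-expressed genes
#'
#' A gene is removed when the given percentile (default the 95th) of its log2
#' expression, computed across ALL samples of the joint meta-set, is strictly
#' below `threshold` (default 7 log2 units). This reproduces the exclusion of
#' genes whose expression never rises meaningfully above background. The
#' percentile uses linear interpolation between order statistics
#' (`stats::quantile()` type 7); this rule is frozen here and used everywhere.
#'
#' @param m Gene-level `expr_matrix` spanning the joint meta-set.
#' @param percentile Percentile as a fraction in (0, 1); default 0.95.
#' @param threshold Log2 expression threshold; default 7.
#' @return A list with `expression` (the filtered `expr_matrix`) and
#'   `removed` (character vector of removed gene identifiers).
#' @export
filter_low_expression <- function(m, percentile = 0.95, threshold = 7.0) {
  stopifnot(percentile > 0, percentile < 1)
  q <- apply(m$values, 1L, stats::quantile, probs = percentile,
             names = FALSE, type = 7)
  removed <- features_of(m)[q < threshold]
  kept <- m$values[!(features_of(m) %in% removed), , drop = FALSE]
  if (nrow(kept) == 0L) stop("all genes removed by the low-expression filter")
  list(expression = expression_matrix(kept, m$cohort), removed = removed)
}
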