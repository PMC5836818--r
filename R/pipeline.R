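#' Assemble and validate a pipeline run configuration
#'
#' All defaults are explicit in the returned object (and hence in the run
#' manifest). `cohorts` maps cohort names to their expression and clinical
#' file paths; `roles` assigns exactly one training cohort, at least one
#' filtration cohort and one testing cohort.
#'
#' @param cohorts Named list; each element a list with `expression` (path),
#'   `clinical` (path) and optionally `dialect` (`"tsv"` or
#'   `"series_matrix"`).
#' @param roles List with `training`, `filtration`, `testing` cohort names.
#' @param family Character vector of the gene family to search.
#' @param probe_annotation Optional path to a probe-to-gene annotation TSV;
#'   when given, probes are collapsed to genes before filtering.
#' @param percentile,expression_threshold Low-expression filter settings.
#' @param train_threshold,filter_threshold Filtration AUC thresholds (must lie
#'   in `[0.5, 1]`).
#' @param cost SVM cost parameter.
#' @param sizes,include_full Subset enumeration settings.
#' @param n_permutations Permutations per strategy for the top survivor
#'   (0 disables the permutation stage).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohorts, roles, family, probe_annotation = NULL,
                       percentile = 0.95, expression_threshold = 7.0,
                       train_threshold = 0.6, filter_threshold = 0.55,
                       cost = 1, sizes = c(1L, 2L, 3L), include_full = TRUE,
                       n_permutations = 0L, seed = 1L, out_dir = "progsig_run") {
  if (length(roles$training) != 1L || length(roles$testing) != 1L ||
      length(roles$filtration) < 1L) {
    stop("config error: need exactly one training, one testing and >= 1 filtration cohort")
  }
  all_roles <- c(roles$training, roles$filtration, roles$testing)
  if (!is.null(cohorts) && !all(all_roles %in% names(cohorts))) {
    stop("config error: no files for cohort(s): ",
         paste(setdiff(all_roles, names(cohorts)), collapse = ", "))
  }
  for (th in c(train_threshold, filter_threshold)) {
    if (th < 0.5 || th > 1) stop("config error: AUC thresholds must lie in [0.5, 1]")
  }
  structure(list(cohorts = cohorts, roles = roles, family = family,
                 probe_annotation = probe_annotation,
                 percentile = percentile,
                 expression_threshold = expression_threshold,
                 train_threshold = train_threshold,
                 filter_threshold = filter_threshold, cost = cost,
                 sizes = as.integer(sizes), include_full = include_full,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds the arguments of [run_config()] (cohort file paths are
#' resolved relative to the config file's directory).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  raw$cohorts <- lapply(raw$cohorts, function(ch) {
    ch$expression <- file.path(base, ch$expression)
    ch$clinical <- file.path(base, ch$clinical)
    ch
  })
  if (!is.null(raw$probe_annotation)) {
    raw$probe_annotation <- file.path(base, raw$probe_annotation)
  }
  raw$roles <- as.list(raw$roles)
  do.call(run_config, raw)
}

load_meta_from_config <- function(cfg) {
  if (is.null(cfg$cohorts)) {
    stop("config lists no cohort files and no meta-set was supplied")
  }
  exprs <- lapply(names(cfg$cohorts), function(ch) {
    spec <- cfg$cohorts[[ch]]
    dialect <- if (is.null(spec$dialect)) "tsv" else spec$dialect
    read_expression(spec$expression, ch, dialect)
  })
  joint <- combine_cohorts(exprs)
  check_cohort_scale(joint)
  if (!is.null(cfg$probe_annotation)) {
    joint <- collapse_probes(joint, read_probe_table(cfg$probe_annotation))
  }
  filtered <- filter_low_expression(joint, cfg$percentile,
                                    cfg$expression_threshold)
  clinical <- lapply(cfg$cohorts, function(spec) read_clinical(spec$clinical))
  meta <- meta_set(filtered$expression, clinical, cfg$roles,
                   family = cfg$family)
  attr(meta, "removed_genes") <- filtered$removed
  meta
}

#' Run the full analysis pipeline
#'
#' ingest -> label -> exhaustive subset search -> (optional) permutation test
#' of the top survivor -> report. Writes into `cfg$out_dir`:
#' `cohort_summary.tsv`, `removed_genes.txt`, `subset_report.tsv`, per-survivor
#' classifier JSON plus testing-cohort ROC and KM coordinate TSVs (under
#' `survivors/`), `permutation_<genes>.json` when requested, and
#' `manifest.json` (config, seed, config hash, package version). Reruns with
#' the same config and seed produce identical outputs.
#'
#' @param cfg A `run_config`, or a path to a YAML/JSON config file.
#' @param meta Optionally a pre-built `meta_set` (skips file ingestion; used
#'   by the synthetic-data path).
#' @return The output directory, invisibly; the `search_result` is attached
#'   as attribute `"search"`.
#' @export
run_pipeline <- function(cfg, meta = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stage <- "ingest"
  result <- tryCatch({
    if (is.null(meta)) meta <- load_meta_from_config(cfg)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "cohort_summary"
    summ <- cohort_summary(meta$labelings)
    utils::write.table(summ, file.path(cfg$out_dir, "cohort_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    removed <- attr(meta, "removed_genes")
    writeLines(if (is.null(removed)) character(0L) else removed,
               file.path(cfg$out_dir, "removed_genes.txt"))

    stage <- "search"
    res <- run_search(meta, sizes = cfg$sizes,
                      include_full = cfg$include_full, cost = cfg$cost,
                      train_threshold = cfg$train_threshold,
                      filter_threshold = cfg$filter_threshold)
    write_search_report(res, file.path(cfg$out_dir, "subset_report.tsv"))

    stage <- "survivor_outputs"
    surv_dir <- file.path(cfg$out_dir, "survivors")
    dir.create(surv_dir, showWarnings = FALSE)
    test_lab <- meta$labelings[[meta$roles$testing]]
    for (ev in res$evaluations) {
      if (!ev$verdict$passed) next
      tag <- paste(ev$gene_set, collapse = "-")
      write_classifier(ev$classifier,
                       file.path(surv_dir, paste0(tag, "_classifier.json")))
      ids <- c(test_lab$positives, test_lab$negatives)
      scores <- decision_scores(ev$classifier, meta$expression, ids)
      roc <- roc_auc(scores, names(scores) %in% test_lab$positives)
      write_roc_tsv(roc, file.path(surv_dir, paste0(tag, "_roc_test.tsv")))
      kmc <- suppressWarnings(km_comparison(ev$classifier, meta))
      for (grp in names(kmc$curves)) {
        write_km_tsv(kmc$curves[[grp]],
                     file.path(surv_dir, paste0(tag, "_km_", grp, ".tsv")))
      }
    }

    stage <- "permutation"
    survivors <- res$report[res$report$passed, , drop = FALSE]
    if (cfg$n_permutations > 0L && nrow(survivors) > 0L) {
      genes <- strsplit(survivors$gene_set[1L], ",", fixed = TRUE)[[1L]]
      pt <- permutation_test(genes, meta, n = cfg$n_permutations,
                             seed = cfg$seed, cost = cfg$cost)
      write_permutation_result(
        pt, file.path(cfg$out_dir,
                      paste0("permutation_", paste(genes, collapse = "-"),
                             ".json")))
    }

    stage <- "manifest"
    cfg_path <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    # hash the analysis settings only: where outputs land must not change
    # the fingerprint of what was computed
    hashable <- unclass(cfg)
    hashable$out_dir <- NULL
    hash_file <- tempfile(fileext = ".json")
    jsonlite::write_json(hashable, hash_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    config_md5 <- unname(tools::md5sum(hash_file))
    unlink(hash_file)
    manifest <- list(
      package = "progsig",
      version = as.character(utils::packageVersion("progsig")),
      seed = cfg$seed,
      config_md5 = config_md5,
      n_subsets = nrow(res$report),
      n_survivors = sum(res$report$passed)
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out <- cfg$out_dir
  attr(out, "search") <- result
  invisible(out)
}
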