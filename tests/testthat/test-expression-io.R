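test_that("TSV and series-matrix dialects round-trip the same values", {
  set.seed(101)
  vals <- matrix(round(rnorm(6, 8, 1.5), 4), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  m <- expression_matrix(vals, "train")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  smx <- withr::local_tempfile(fileext = ".txt")
  write_expression(m, tsv, "tsv")
  write_expression(m, smx, "series_matrix")

  m_tsv <- read_expression(tsv, "train", "tsv")
  m_smx <- read_expression(smx, "train", "series_matrix")
  expect_identical(dim(m_tsv$values), c(3L, 2L))
  expect_equal(m_tsv$values, vals, tolerance = 1e-6)
  expect_identical(m_smx$values, m_tsv$values)
  expect_identical(m_smx$cohort, m_tsv$cohort)
})

test_that("series-matrix reader tolerates quoted identifiers and metadata lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    '!Series_title "synthetic fixture"',
    "!series_matrix_table_begin",
    paste("\"ID_REF\"", "\"S1\"", "\"S2\"", sep = "\t"),
    paste("\"P1\"", "8.25", "7.5", sep = "\t"),
    paste("\"P2\"", "6.0", "6.125", sep = "\t"),
    "!series_matrix_table_end",
    "!extra trailing line"), path)
  m <- read_expression(path, "c1", "series_matrix")
  expect_identical(features_of(m), c("P1", "P2"))
  expect_equal(m$values["P1", "S2"], 7.5)
})

test_that("malformed input yields parse errors naming the offending position", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1.5\toops"), path)
  expect_error(read_expression(path, "c"), "line 2.*oops.*S2")

  writeLines(c("gene_id\tS1\tS2", "G1\t1.5"), path)
  expect_error(read_expression(path, "c"), "expected 3 fields")

  writeLines("gene_id\tS1\tS2", path)
  expect_error(read_expression(path, "c"), "empty data section")

  writeLines(c("!series_matrix_table_begin", "gene_id\tS1",
               "!series_matrix_table_end"), path)
  expect_error(read_expression(path, "c", "series_matrix"),
               "empty data section")
})

test_that("expression_matrix enforces its invariants", {
  vals <- matrix(1:4, 2, dimnames = list(c("G1", "G1"), c("S1", "S2")))
  expect_error(expression_matrix(vals, "c"), "duplicate feature")
  vals <- matrix(c(1, NA, 3, 4), 2,
                 dimnames = list(c("G1", "G2"), c("S1", "S2")))
  expect_error(expression_matrix(vals, "c"), "non-finite.*G2.*S1")
})

make_probe_matrix <- function(order = c("PA", "PB")) {
  # PA mean 8.2, PB mean 6.1, both map to GENE1; PC alone maps to GENE2
  rows <- list(PA = c(8.0, 8.4), PB = c(6.0, 6.2), PC = c(5.0, 5.5))
  vals <- do.call(rbind, rows[c(order, "PC")])
  colnames(vals) <- c("S1", "S2")
  expression_matrix(vals, "c")
}

probe_tab <- data.frame(probe_id = c("PA", "PB", "PC"),
                        gene_id = c("GENE1", "GENE1", "GENE2"),
                        stringsAsFactors = FALSE)

test_that("collapse_probes keeps the highest-mean probe per gene", {
  g <- collapse_probes(make_probe_matrix(), probe_tab)
  expect_identical(features_of(g), c("GENE1", "GENE2"))
  expect_equal(unname(g$values["GENE1", ]), c(8.0, 8.4))  # the 8.2-mean probe
  expect_equal(unname(g$values["GENE2", ]), c(5.0, 5.5))  # single probe kept
})

test_that("collapse_probes breaks mean ties by smallest probe_id, in any row order", {
  tie_tab <- data.frame(probe_id = c("PX", "PA"), gene_id = "GENE1",
                        stringsAsFactors = FALSE)
  build <- function(order) {
    rows <- list(PX = c(7.0, 9.0), PA = c(9.0, 7.0))  # equal means
    vals <- do.call(rbind, rows[order])
    colnames(vals) <- c("S1", "S2")
    expression_matrix(vals, "c")
  }
  g1 <- collapse_probes(build(c("PX", "PA")), tie_tab)
  g2 <- collapse_probes(build(c("PA", "PX")), tie_tab)
  expect_identical(g1$values, g2$values)
  expect_equal(unname(g1$values["GENE1", ]), c(9.0, 7.0))  # PA < PX wins
})

test_that("collapse_probes is idempotent and rejects unannotated probes", {
  g <- collapse_probes(make_probe_matrix(), probe_tab)
  ident <- data.frame(probe_id = features_of(g), gene_id = features_of(g),
                      stringsAsFactors = FALSE)
  expect_identical(collapse_probes(g, ident)$values, g$values)
  expect_error(collapse_probes(make_probe_matrix(), probe_tab[-2, ]),
               "missing from annotation: PB")
})

test_that("low-expression filter removes genes with 95th percentile strictly below 7", {
  vals <- rbind(
    below = rep(6.9, 40),       # 95th percentile 6.9 -> removed
    boundary = rep(7.0, 40),    # exactly 7 -> retained ("less than" is strict)
    high = rep(9.0, 40))
  colnames(vals) <- sprintf("S%02d", 1:40)
  f <- filter_low_expression(expression_matrix(vals, "c"))
  expect_identical(f$removed, "below")
  expect_identical(features_of(f$expression), c("boundary", "high"))
})

test_that("the percentile rule matches a direct order-statistic computation", {
  # 100 samples: 96 at 5.0, 4 at 10.0; type-7 interpolation at p=0.95:
  # h = 1 + 0.95*99 = 95.05 -> x_(95) + 0.05*(x_(96)-x_(95)) = 5.0 -> removed
  x <- c(rep(5.0, 96), rep(10.0, 4))
  xs <- sort(x)
  h <- 1 + 0.95 * (length(x) - 1)
  oracle <- xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
  expect_equal(oracle, 5.0)

  set.seed(5)
  vals <- rbind(spiky = sample(x), ref = rep(8, 100))
  colnames(vals) <- sprintf("S%03d", 1:100)
  f <- filter_low_expression(expression_matrix(vals, "c"))
  expect_identical(f$removed, "spiky")
})

test_that("the filtered set does not depend on gene order", {
  set.seed(42)
  vals <- matrix(rnorm(30 * 25, 7, 1), 30,
                 dimnames = list(sprintf("G%02d", 1:30), sprintf("S%02d", 1:25)))
  m <- expression_matrix(vals, "c")
  perm <- sample(30)
  m_perm <- expression_matrix(vals[perm, ], "c")
  expect_setequal(filter_low_expression(m)$removed,
                  filter_low_expression(m_perm)$removed)
})

test_that("combine_cohorts aligns features and flags scale mismatches", {
  v1 <- matrix(c(8, 9, 7, 8), 2, dimnames = list(c("G1", "G2"), c("A1", "A2")))
  v2 <- matrix(c(7.5, 8.5), 2, dimnames = list(c("G2", "G1"), "B1"))
  joint <- combine_cohorts(expression_matrix(v1, "c1"),
                           expression_matrix(v2, "c2"))
  expect_identical(features_of(joint), c("G1", "G2"))
  expect_equal(unname(joint$values["G1", "B1"]), 8.5)  # realigned
  expect_identical(unname(joint$cohort), c("c1", "c1", "c2"))

  v3 <- matrix(c(3, 4), 2, dimnames = list(c("G1", "G2"), "D1"))
  shifted <- combine_cohorts(expression_matrix(v1, "c1"),
                             expression_matrix(v3, "c3"))
  expect_warning(check_cohort_scale(shifted), "one normalized scale")
})

test_that("the shipped synthetic fixture walks the ingest path end to end", {
  ext <- system.file("extdata", package = "progsig")
  m <- read_expression(file.path(ext, "synthetic_series_matrix.txt"),
                       cohort = "demo", dialect = "series_matrix")
  expect_identical(dim(m$values), c(5L, 4L))
  g <- collapse_probes(m, read_probe_table(
    file.path(ext, "synthetic_probe_annotation.tsv")))
  # GENE_A keeps its higher-mean probe (200001_at over 200002_s_at)
  expect_identical(features_of(g), c("GENE_A", "GENE_B", "GENE_C", "GENE_D"))
  expect_equal(unname(g$values["GENE_A", "SAMPLE_01"]), 8.412)
  f <- filter_low_expression(g)
  expect_setequal(f$removed, c("GENE_C", "GENE_D"))
  lab <- label_cohort(read_clinical(file.path(ext, "synthetic_clinical.tsv")))
  expect_identical(lab$positives, "SAMPLE_01")
  expect_identical(lab$negatives, "SAMPLE_02")
  expect_setequal(lab$excluded$reason, c("short_followup", "late_recurrence"))
})
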