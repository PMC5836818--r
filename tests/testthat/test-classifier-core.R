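# expression fixture: one matrix, samples P* positive (recurrence), N* negative
expr_fixture <- function(values) {
  expression_matrix(values, "train")
}

sep_1gene <- function() {
  vals <- matrix(c(9.1, 8.8, 9.4, 6.2, 6.0, 5.8), nrow = 1,
                 dimnames = list("G1", c("P1", "P2", "P3", "N1", "N2", "N3")))
  expr_fixture(vals)
}

test_that("separation forces the sign convention: high expression in recurrence => positive weight", {
  x <- sep_1gene()
  clf <- train_linear_svm(x, c("P1", "P2", "P3"), c("N1", "N2", "N3"))
  expect_gt(clf$weights[["G1"]], 0)
  scores <- decision_scores(clf, x)
  expect_true(min(scores[c("P1", "P2", "P3")]) >
              max(scores[c("N1", "N2", "N3")]))
})

test_that("swapping class meaning negates the weight without changing its size", {
  x <- sep_1gene()
  clf_fwd <- train_linear_svm(x, c("P1", "P2", "P3"), c("N1", "N2", "N3"))
  clf_rev <- train_linear_svm(x, c("N1", "N2", "N3"), c("P1", "P2", "P3"))
  expect_lt(clf_rev$weights[["G1"]], 0)
  expect_equal(abs(clf_rev$weights[["G1"]]), abs(clf_fwd$weights[["G1"]]),
               tolerance = 1e-6)
})

test_that("the separator matches a brute-force margin maximizer on a 2-gene toy set", {
  # 6 separable points; high cost approximates the hard-margin solution
  pts <- rbind(c(2.0, 2.2), c(2.5, 3.0), c(3.0, 2.0),
               c(0.0, 0.2), c(0.5, -0.5), c(-0.5, 0.5))
  vals <- t(pts)
  dimnames(vals) <- list(c("G1", "G2"),
                         c("P1", "P2", "P3", "N1", "N2", "N3"))
  x <- expr_fixture(vals)
  clf <- train_linear_svm(x, c("P1", "P2", "P3"), c("N1", "N2", "N3"),
                          cost = 1e4)

  # oracle works in the same standardized space the classifier is fit in
  feats <- t(vals)
  zs <- scale(feats)
  oracle <- max_margin_oracle(zs, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  w_hat <- clf$weights / sqrt(sum(clf$weights^2))
  expect_equal(unname(w_hat), oracle$w, tolerance = 5e-3)
  # hard-margin geometry: |w| = 1/margin, bias scales accordingly
  expect_equal(sqrt(sum(clf$weights^2)), 1 / oracle$margin, tolerance = 1e-2)
  expect_equal(clf$bias, oracle$b / oracle$margin, tolerance = 1e-2)
})

test_that("decision scores are the documented affine form of standardized expression", {
  vals <- matrix(c(8.0, 7.0, 6.0, 5.5, 7.5, 6.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
  x <- expr_fixture(vals)
  clf <- structure(list(gene_ids = c("G1", "G2"),
                        weights = c(G1 = 0.7, G2 = -0.4), bias = 0.1,
                        center = c(G1 = 7.0, G2 = 6.5),
                        scale = c(G1 = 1.0, G2 = 0.5), cost = 1,
                        training_cohort = "train"),
                   class = "linear_classifier")
  manual <- 0.7 * (vals["G1", ] - 7.0) / 1.0 -
    0.4 * (vals["G2", ] - 6.5) / 0.5 + 0.1
  expect_equal(decision_scores(clf, x), manual, tolerance = 1e-9)

  zero_w <- clf
  zero_w$weights[] <- 0
  expect_equal(unname(decision_scores(zero_w, x)), rep(0.1, 3))
  expect_equal(raw_weights(clf), c(G1 = 0.7, G2 = -0.8))
})

test_that("gene order permutation permutes weights and leaves scores unchanged", {
  set.seed(21)
  vals <- matrix(rnorm(4 * 20, 8, 1.5), nrow = 4,
                 dimnames = list(paste0("G", 1:4), paste0("S", 1:20)))
  x <- expr_fixture(vals)
  pos <- paste0("S", 1:10); neg <- paste0("S", 11:20)
  clf1 <- train_linear_svm(x, pos, neg, genes = c("G1", "G2", "G3", "G4"))
  clf2 <- train_linear_svm(x, pos, neg, genes = c("G3", "G1", "G4", "G2"))
  expect_equal(clf2$weights[clf1$gene_ids], clf1$weights, tolerance = 1e-9)
  expect_equal(decision_scores(clf2, x), decision_scores(clf1, x),
               tolerance = 1e-9)
})

test_that("a constant shift of one gene is absorbed by centering", {
  set.seed(22)
  vals <- matrix(rnorm(2 * 16, 8, 1.5), nrow = 2,
                 dimnames = list(c("G1", "G2"), paste0("S", 1:16)))
  pos <- paste0("S", 1:8); neg <- paste0("S", 9:16)
  shifted <- vals
  shifted["G1", ] <- shifted["G1", ] + 3
  clf_a <- train_linear_svm(expr_fixture(vals), pos, neg)
  clf_b <- train_linear_svm(expr_fixture(shifted), pos, neg)
  s_a <- decision_scores(clf_a, expr_fixture(vals))
  s_b <- decision_scores(clf_b, expr_fixture(shifted))
  expect_equal(rank(s_a), rank(s_b))
  expect_equal(s_a, s_b, tolerance = 1e-6)
})

test_that("duplicating every training sample leaves the separator unchanged at high cost", {
  x <- sep_1gene()
  vals2 <- cbind(x$values, x$values)
  colnames(vals2) <- c(colnames(x$values), paste0(colnames(x$values), "_dup"))
  x2 <- expr_fixture(vals2)
  pos <- c("P1", "P2", "P3"); neg <- c("N1", "N2", "N3")
  clf <- train_linear_svm(x, pos, neg, cost = 1e3)
  clf2 <- train_linear_svm(x2, c(pos, paste0(pos, "_dup")),
                           c(neg, paste0(neg, "_dup")), cost = 1e3)
  # the separator (decision function over samples) is what must not move;
  # standardized-space weights rescale because the sample sd changes with n
  expect_equal(decision_scores(clf2, x), decision_scores(clf, x),
               tolerance = 1e-3)
  expect_equal(raw_weights(clf2), raw_weights(clf), tolerance = 1e-3)
})

test_that("degenerate training inputs are rejected or flagged", {
  x <- sep_1gene()
  expect_error(train_linear_svm(x, c("P1", "P2", "P3"), character(0)),
               "at least 2 samples")
  expect_error(train_linear_svm(x, "P1", c("N1", "N2")), "at least 2 samples")
  flat <- expr_fixture(matrix(
    c(rep(5, 6), 9.1, 8.8, 9.4, 6.2, 6.0, 5.8), nrow = 2, byrow = TRUE,
    dimnames = list(c("GF", "G1"), c("P1", "P2", "P3", "N1", "N2", "N3"))))
  expect_warning(
    clf <- train_linear_svm(flat, c("P1", "P2", "P3"), c("N1", "N2", "N3")),
    "zero-variance")
  expect_identical(unname(clf$scale["GF"]), 1)
  expect_error(decision_scores(clf, sep_1gene()), "absent")
})

test_that("classifier JSON serialization round-trips", {
  x <- sep_1gene()
  clf <- train_linear_svm(x, c("P1", "P2", "P3"), c("N1", "N2", "N3"),
                          cost = 2, training_cohort = "train")
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  back <- read_classifier(path)
  expect_equal(back$weights, clf$weights)
  expect_equal(back$bias, clf$bias)
  expect_equal(back$center, clf$center)
  expect_equal(back$cost, 2)
  expect_equal(decision_scores(back, x), decision_scores(clf, x))
})
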