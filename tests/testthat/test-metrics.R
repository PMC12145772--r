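# Evaluation statistics: confusion counts, the five threshold metrics,
# ROC/AUC, cross-validation consistency, and the paired error protocol.

test_that("confusion counts match direct tallying", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unclass(cm)[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  all_right <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(all_right$FP + all_right$FN, 0L)

  set.seed(101)
  y <- sample(0:1, 1000, replace = TRUE)
  p <- sample(0:1, 1000, replace = TRUE)
  expect_identical(unclass(confusion(y, p))[c("TP", "TN", "FP", "FN")],
                   oracle_confusion(y, p)[c("TP", "TN", "FP", "FN")])

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("the five threshold metrics match their defining formulas", {
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1, 1))

  m <- compute_metrics(list(TP = 40, TN = 30, FP = 20, FN = 10))
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.6)
  expect_equal(m[["f1"]], 80 / 110)
  expect_equal(m[["mcc"]], 1000 / sqrt(60 * 50 * 50 * 40))

  anti <- compute_metrics(list(TP = 0, TN = 0, FP = 50, FN = 50))
  expect_equal(anti[["mcc"]], -1)

  set.seed(102)
  for (i in 1:200) {
    counts <- as.list(setNames(rpois(4, 20) + 1L, c("TP", "TN", "FP", "FN")))
    expect_equal(as.numeric(compute_metrics(counts)),
                 as.numeric(oracle_metrics(counts$TP, counts$TN, counts$FP, counts$FN)),
                 tolerance = 1e-10)
  }
})

test_that("zero denominators are flagged and reported as 0", {
  expect_warning(m <- compute_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0)),
                 "zero denominator")
  expect_equal(m[["sensitivity"]], 0)
  expect_true("sensitivity" %in% attr(m, "degenerate"))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("accuracy decomposes as the class-weighted mean of Sn and Sp", {
  set.seed(103)
  for (i in 1:100) {
    counts <- as.list(setNames(rpois(4, 15) + 1L, c("TP", "TN", "FP", "FN")))
    m <- compute_metrics(counts)
    P <- counts$TP + counts$FN; N <- counts$TN + counts$FP
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("complementation symmetries of the confusion metrics hold", {
  set.seed(104)
  y <- sample(0:1, 400, replace = TRUE)
  p <- sample(0:1, 400, replace = TRUE)
  m <- compute_metrics(confusion(y, p))
  # complementing both labels and predictions swaps Sn and Sp, MCC invariant
  m_both <- compute_metrics(confusion(1 - y, 1 - p))
  expect_equal(m_both[["sensitivity"]], m[["specificity"]])
  expect_equal(m_both[["specificity"]], m[["sensitivity"]])
  expect_equal(m_both[["mcc"]], m[["mcc"]])
  # complementing the predictions alone flips the MCC sign
  m_pred <- compute_metrics(confusion(y, 1 - p))
  expect_equal(m_pred[["mcc"]], -m[["mcc"]], tolerance = 1e-12)
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)

  set.seed(105)
  y <- sample(0:1, 300, replace = TRUE)
  s <- round(runif(300), 2)              # rounding forces ties
  expect_equal(roc_auc(y, s)$auc, oracle_auc(y, s), tolerance = 1e-10)

  skip_if_not_installed("pROC")
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("the ROC curve is monotone and integrates to the rank AUC", {
  set.seed(106)
  y <- sample(0:1, 200, replace = TRUE)
  s <- round(runif(200), 1)
  r <- roc_auc(y, s)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  trap <- sum(diff(r$curve$fpr) *
              (utils::head(r$curve$tpr, -1) + utils::tail(r$curve$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(107)
  y <- sample(0:1, 150, replace = TRUE)
  s <- rnorm(150)
  a <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, a)
  expect_equal(roc_auc(y, 3 * s - 7)$auc, a)

  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("pipeline cross-validation is internally consistent", {
  ds <- generate_dataset(60, 60, motif = motif_model(effect_size = "strong"),
                         seed = 111)
  cv <- cross_validate(ds, encoders = c("nac", "ncp"), classifiers = "LR",
                       n_folds = 3, inner_folds = 3, seed = 7)
  expect_identical(nrow(cv$per_fold), 3L)
  expect_false(anyNA(cv$predictions))
  expect_gt(cv$mean[["auc"]], 0.85)
  # fold rows are recomputable from the stored per-record predictions
  fold <- methylstack:::stratified_folds(ds$label, 3, 7 + 271L)
  for (f in 1:3) {
    te <- fold == f
    expect_equal(unname(cv$per_fold[f, ]),
                 unname(evaluate_predictions(ds$label[te], cv$predictions[te])))
  }
})

test_that("cross-species diagonals equal the single-species evaluation", {
  pair <- generate_species_pair(shared_motif = TRUE, n_train = 50,
                                n_independent = 30, seed = 5)
  mats <- cross_species_matrix(pair, encoders = "ncp", classifiers = "LR",
                               n_folds = 3, seed = 9)
  fitA <- methylstack(pair$speciesA$train, encoders = "ncp",
                      classifiers = "LR", n_folds = 3, seed = 9)
  selfA <- evaluate_predictions(pair$speciesA$independent$label,
                                predict(fitA, pair$speciesA$independent))
  for (m in names(mats)) {
    expect_equal(mats[[m]]["speciesA", "speciesA"], selfA[[m]],
                 tolerance = 1e-12, label = m)
  }
  expect_error(cross_species_matrix(list(a = list(train = NULL))), ">= 2")
})

test_that("the paired absolute-error protocol follows its conventions", {
  set.seed(121)
  y <- rep(c(0L, 1L), 50)
  stacked <- as.numeric(y)               # perfect stacked model
  base <- matrix(0.5, 100, 1, dimnames = list(NULL, "const_base"))
  res <- absolute_error_tests(y, stacked, base)
  expect_equal(res$delta, -0.5)
  expect_true(is.na(res$t_p))            # zero-variance differences
  expect_lt(res$wilcoxon_p, 0.01)
  expect_true(res$applicable)

  # base identical to stacked: all differences zero, not applicable
  res2 <- absolute_error_tests(y, stacked, matrix(stacked, 100, 1))
  expect_equal(res2$delta, 0)
  expect_false(res2$applicable)
  expect_true(is.na(res2$t_p) && is.na(res2$wilcoxon_p))

  # genuine noisy improvement is detected by both tests
  probs <- pmin(pmax(ifelse(y == 1, 0.8, 0.2) + rnorm(100, 0, 0.05), 0), 1)
  worse <- pmin(pmax(probs + ifelse(y == 1, -0.2, 0.2) + rnorm(100, 0, 0.05), 0), 1)
  res3 <- absolute_error_tests(y, probs, cbind(worse = worse))
  expect_lt(res3$delta, 0)
  expect_lt(res3$t_p, 0.001)
  expect_lt(res3$wilcoxon_p, 0.001)

  expect_error(absolute_error_tests(y, stacked[1:10], base), "aligned")
})

test_that("Holm adjustment is applied across base columns when requested", {
  set.seed(122)
  y <- rep(c(0L, 1L), 30)
  stacked <- pmin(pmax(y + rnorm(60, 0, 0.1), 0), 1)
  base <- cbind(a = runif(60), b = runif(60), c = runif(60))
  raw <- absolute_error_tests(y, stacked, base)
  adj <- absolute_error_tests(y, stacked, base, adjust = "holm")
  expect_true(all(adj$t_p >= raw$t_p - 1e-15))
})
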