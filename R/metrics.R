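# Evaluation statistics: 2x2 confusion counts, the five threshold
# metrics (accuracy, sensitivity, specificity, F1, Matthews correlation),
# ROC/AUC with the Mann-Whitney tie convention, cross-validation of the
# full pipeline, cross-species transfer matrices, and the paired
# significance protocol on absolute prediction errors.

#' Confusion counts for binary predictions
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return list of class `m5c_confusion` with integer fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length")
  }
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1")
  }
  structure(list(TP = sum(labels == 1 & predicted == 1),
                 TN = sum(labels == 0 & predicted == 0),
                 FP = sum(labels == 0 & predicted == 1),
                 FN = sum(labels == 1 & predicted == 0)),
            class = "m5c_confusion")
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), F1 = 2TP/(2TP+FN+FP) and the Matthews
#' correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as 0 and flagged in the
#' `degenerate` attribute (with a warning).
#'
#' @param c an [confusion()] result, or a list with fields TP, TN, FP, FN.
#' @return named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `mcc`.
#' @export
compute_metrics <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(
    accuracy    = (TP + TN) / total,
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    f1          = safe_div(2 * TP, 2 * TP + FN + FP),
    mcc         = {
      den <- sqrt(as.double(TP + FP)) * sqrt(as.double(TP + FN)) *
             sqrt(as.double(TN + FP)) * sqrt(as.double(TN + FN))
      if (den == 0) NA_real_ else (as.double(TP) * TN - as.double(FP) * FN) / den
    }
  )
  degenerate <- names(out)[is.na(out)]
  if (length(degenerate)) {
    warning("zero denominator for: ", paste(degenerate, collapse = ", "),
            "; reported as 0")
    out[is.na(out)] <- 0
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) formula, so it equals the
#' probability that a random positive outscores a random negative, with
#' ties counted one half. Curve points come from a threshold sweep over
#' the unique scores; trapezoidal integration of the curve reproduces the
#' rank AUC exactly.
#'
#' @param labels true 0/1 labels (both classes required).
#' @param scores numeric scores, higher = more positive.
#' @return list with `auc` and a data frame `curve` of (fpr, tpr) points,
#'   monotone in both coordinates, from (0, 0) to (1, 1).
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC requires both classes")
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- !duplicated(sc)                 # collapse tied scores into one step
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  keep <- c(which(grp)[-1L] - 1L, length(sc))
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, curve = curve)
}

#' Full metric panel for scored predictions
#'
#' @param labels true 0/1 labels.
#' @param scores probabilities/scores.
#' @param threshold threshold for the 2x2 metrics (default 0.5).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, `mcc`, `auc`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  m <- compute_metrics(confusion(labels, as.integer(scores >= threshold)))
  c(m, auc = roc_auc(labels, scores)$auc)
}

#' Cross-validate the full stacking pipeline
#'
#' Outer stratified k-fold cross-validation in which the entire pipeline
#' (base-model grid plus meta-classifier) is retrained inside every
#' outer-training split and evaluated on the held-out fold, so no
#' held-out record influences any level of the model scoring it.
#'
#' @param dataset labeled [m5c_dataset].
#' @param encoders,classifiers,meta,n_folds,seed as in [methylstack()];
#'   `n_folds` is the outer fold count (the inner out-of-fold split uses
#'   `inner_folds`).
#' @param inner_folds folds for the meta-feature construction inside each
#'   outer-training split (default 5).
#' @return list with `per_fold` (matrix of metric rows per fold), `mean`
#'   (mean metric vector), and `predictions` (per-record out-of-fold
#'   stacked probabilities).
#' @export
cross_validate <- function(dataset, encoders = default_encoders(),
                           classifiers = default_classifiers(),
                           meta = classifier_spec("RF"),
                           n_folds = 5L, inner_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "m5c_dataset"))
  y <- dataset$label
  if (anyNA(y)) stop("cross_validate requires labels")
  fold <- stratified_folds(y, n_folds, seed + 271L)
  probs <- rep(NA_real_, length(y))
  per_fold <- NULL
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[te])) < 2L) stop("fold ", f, " lacks one class")
    fit <- methylstack(dataset[tr], encoders = encoders,
                       classifiers = classifiers, meta = meta,
                       n_folds = inner_folds, seed = seed + f)
    probs[te] <- predict(fit, dataset[te], type = "prob")
    per_fold <- rbind(per_fold, evaluate_predictions(y[te], probs[te]))
  }
  rownames(per_fold) <- paste0("fold", seq_len(n_folds))
  list(per_fold = per_fold, mean = colMeans(per_fold), predictions = probs)
}

#' Cross-species transfer evaluation matrix
#'
#' Trains the pipeline on each tagged species' training set and evaluates
#' it on every tagged species' independent set (including its own), the
#' standard design for asking whether a model trained on one species
#' transfers to another.
#'
#' @param species named list; each element a list with components `train`
#'   and `independent`, both labeled [m5c_dataset]s.
#' @param encoders,classifiers,meta,n_folds,seed as in [methylstack()].
#' @return list of six tag-by-tag matrices (`accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `mcc`, `auc`); rows = training species,
#'   columns = evaluation species.
#' @export
cross_species_matrix <- function(species, encoders = default_encoders(),
                                 classifiers = default_classifiers(),
                                 meta = classifier_spec("RF"),
                                 n_folds = 5L, seed = 1L) {
  stopifnot(is.list(species), length(species) >= 2L, !is.null(names(species)))
  for (tag in names(species)) {
    if (!all(c("train", "independent") %in% names(species[[tag]]))) {
      stop("species '", tag, "' is missing a train or independent split")
    }
  }
  tags <- names(species)
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1", "mcc", "auc")
  out <- lapply(metric_names, function(m) {
    matrix(NA_real_, length(tags), length(tags), dimnames = list(tags, tags))
  })
  names(out) <- metric_names
  for (a in tags) {
    fit <- methylstack(species[[a]]$train, encoders = encoders,
                       classifiers = classifiers, meta = meta,
                       n_folds = n_folds, seed = seed)
    for (b in tags) {
      test <- species[[b]]$independent
      metrics <- evaluate_predictions(test$label, predict(fit, test, type = "prob"))
      for (m in metric_names) out[[m]][a, b] <- metrics[[m]]
    }
  }
  out
}

#' Paired significance tests on absolute prediction error
#'
#' For the stacked model and each base-model column, computes the
#' per-record absolute prediction error |probability - label| and tests
#' whether the stacked errors differ from each base model's errors, using
#' a paired two-sided t-test and a Wilcoxon signed-rank test on the
#' per-record differences. Zero differences are dropped before the
#' signed-rank ranking; a zero-variance difference vector makes the
#' t-test (and an all-zero one both tests) not applicable (`NA` p-value
#' with `applicable = FALSE`) rather than p = 1.
#'
#' @param labels true 0/1 labels.
#' @param stacked_probs stacked-model probabilities.
#' @param base_probs matrix of base-model probabilities (one column per
#'   base model) aligned with `labels`.
#' @param adjust p-value adjustment across base models: `"none"`
#'   (default) or `"holm"`.
#' @return data frame with one row per base column: `model`,
#'   `delta` (mean stacked error minus mean base error; negative favors
#'   stacking), `t_p`, `wilcoxon_p`, `applicable`.
#' @export
absolute_error_tests <- function(labels, stacked_probs, base_probs,
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  base_probs <- as.matrix(base_probs)
  n <- length(labels)
  if (length(stacked_probs) != n || nrow(base_probs) != n) {
    stop("labels, stacked probabilities and base columns must be aligned")
  }
  e_stack <- abs(stacked_probs - labels)
  res <- lapply(seq_len(ncol(base_probs)), function(j) {
    e_base <- abs(base_probs[, j] - labels)
    d <- e_stack - e_base
    delta <- mean(d)
    nonzero <- d[d != 0]
    if (length(nonzero) == 0L) {
      return(data.frame(delta = delta, t_p = NA_real_, wilcoxon_p = NA_real_,
                        applicable = FALSE))
    }
    t_p <- if (stats::sd(d) < 1e-15) NA_real_ else
      stats::t.test(d, mu = 0)$p.value
    w_p <- suppressWarnings(stats::wilcox.test(nonzero, mu = 0)$p.value)
    data.frame(delta = delta, t_p = t_p, wilcoxon_p = w_p, applicable = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(model = colnames(base_probs) %||% paste0("base", seq_len(ncol(base_probs))),
               out)
  if (adjust == "holm") {
    out$t_p <- stats::p.adjust(out$t_p, "holm")
    out$wilcoxon_p <- stats::p.adjust(out$wilcoxon_p, "holm")
  }
  rownames(out) <- NULL
  out
}
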