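#' Fit a stacked (or voting) ensemble m5C site predictor
#'
#' The main model-fitting entry point. Encodes the labeled training
#' windows under every encoder in the roster, trains one base classifier
#' per (encoder, classifier) pair, assembles leakage-free out-of-fold
#' probability meta-features, and combines the base models either by
#' stacking (a meta-classifier trained on the out-of-fold matrix; the
#' default, with a random-forest meta-learner) or by hard/soft voting.
#'
#' With the full default rosters this is an 11 x 11 grid of 121 base
#' models; smaller rosters (e.g. 3 encoders x 3 classifiers) fit in
#' seconds on a few hundred records and are recommended for exploration.
#'
#' @param dataset a labeled [m5c_dataset] of cytosine-centered windows.
#' @param encoders list of [encoder_spec()] / encoder names
#'   (default: the full 11-family roster).
#' @param classifiers list of [classifier_spec()] / algorithm names
#'   (default: the full 11-algorithm roster).
#' @param ensemble `"stacking"`, `"voting-soft"` or `"voting-hard"`.
#' @param meta meta-classifier spec or algorithm name (stacking only;
#'   default random forest).
#' @param n_folds stratified folds for the out-of-fold meta-features.
#' @param seed integer seed controlling folds and every model fit.
#' @param threshold decision threshold applied to the final score.
#' @return an object of class `methylstack` with components `grid`,
#'   `ensemble` (the fitted combiner), `mode`, `threshold`, `call`.
#' @seealso [predict.methylstack()], [summary.methylstack()],
#'   [cross_validate()], [generate_dataset()]
#' @examples
#' motif <- motif_model(effect_size = "strong")
#' train <- generate_dataset(60, 60, motif = motif, seed = 1)
#' fit <- methylstack(train, encoders = c("nac", "ncp"),
#'                    classifiers = c("LR", "NB"), seed = 1)
#' test <- generate_dataset(30, 30, motif = motif, seed = 2)
#' head(predict(fit, test))
#' @export
methylstack <- function(dataset,
                        encoders = default_encoders(),
                        classifiers = default_classifiers(),
                        ensemble = c("stacking", "voting-soft", "voting-hard"),
                        meta = classifier_spec("RF"),
                        n_folds = 5L, seed = 1L, threshold = 0.5) {
  ensemble <- match.arg(ensemble)
  grid <- train_grid(dataset, encoders = encoders, classifiers = classifiers,
                     n_folds = n_folds, seed = seed)
  comb <- switch(ensemble,
    "stacking"    = fit_meta(grid, meta = meta),
    "voting-soft" = voting_model(grid, mode = "soft", threshold = threshold),
    "voting-hard" = voting_model(grid, mode = "hard", threshold = threshold)
  )
  structure(list(grid = grid, ensemble = comb, mode = ensemble,
                 threshold = threshold, call = match.call()),
            class = "methylstack")
}

#' Predict m5C probabilities for new windows
#'
#' @param object a fitted [methylstack()] model.
#' @param newdata an [m5c_dataset] of windows with the training window
#'   length.
#' @param type `"prob"` (final ensemble score), `"class"` (0/1 labels at
#'   the model threshold), or `"meta"` (the full base-model probability
#'   matrix, one column per grid cell).
#' @param ... ignored.
#' @return numeric vector (`"prob"`), integer vector (`"class"`), or
#'   matrix (`"meta"`).
#' @export
predict.methylstack <- function(object, newdata,
                                type = c("prob", "class", "meta"), ...) {
  type <- match.arg(type)
  base <- predict_grid(object$grid, newdata)
  if (type == "meta") return(base)
  score <- if (object$mode == "stacking") {
    predict_stacked(object$ensemble, newdata, base_matrix = base)$probability
  } else {
    predict_voting(object$ensemble, newdata, base_matrix = base)$score
  }
  if (type == "prob") score else as.integer(score >= object$threshold)
}

#' @export
print.methylstack <- function(x, ...) {
  cat("methylstack ensemble m5C predictor\n")
  cat(sprintf("  grid: %d encoders x %d classifiers = %d base models\n",
              length(x$grid$encoders), length(x$grid$classifiers),
              length(x$grid$models)))
  cat(sprintf("  combination: %s%s\n", x$mode,
              if (x$mode == "stacking")
                paste0(" (meta = ", x$ensemble$meta_spec$algo, ")") else ""))
  cat(sprintf("  training: n = %d, %d folds, seed = %d\n",
              length(x$grid$labels), x$grid$n_folds, x$grid$seed))
  invisible(x)
}

#' Summarize a fitted ensemble
#'
#' Reports the cross-validated accuracy of every grid cell, the best
#' cell, and the out-of-fold AUC range across base models.
#'
#' @param object a fitted [methylstack()] model.
#' @param ... ignored.
#' @return an object of class `summary.methylstack` (printed as a grid
#'   accuracy table plus headline numbers).
#' @export
summary.methylstack <- function(object, ...) {
  acc <- grid_accuracy(object$grid)
  auc <- grid_column_auc(object$grid)
  best <- which(acc == max(acc), arr.ind = TRUE)[1L, ]
  structure(list(accuracy = acc, oof_auc = auc,
                 best_cell = c(encoder = unname(rownames(acc)[best[1L]]),
                               classifier = unname(colnames(acc)[best[2L]])),
                 mode = object$mode, n = length(object$grid$labels)),
            class = "summary.methylstack")
}

#' @export
print.summary.methylstack <- function(x, ...) {
  cat("Base-model cross-validated accuracy (rows = encoders):\n")
  print(round(x$accuracy, 3))
  cat(sprintf("\nBest cell: %s + %s (accuracy %.3f)\n",
              x$best_cell["encoder"], x$best_cell["classifier"], max(x$accuracy)))
  cat(sprintf("OOF AUC across %d base models: min %.3f, median %.3f, max %.3f\n",
              length(x$oof_auc), min(x$oof_auc),
              stats::median(x$oof_auc), max(x$oof_auc)))
  invisible(x)
}

#' @describeIn methylstack heatmap of the grid's cross-validated accuracy.
#' @param x a fitted `methylstack` model.
#' @export
plot.methylstack <- function(x, ...) {
  plot_grid_accuracy(grid_accuracy(x$grid))
}
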