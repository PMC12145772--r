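# Second-level combination of the base-model grid: stacking (a
# meta-classifier trained on the out-of-fold probability matrix) or
# hard/soft voting over the base-model probabilities.

#' Fit the stacking meta-classifier
#'
#' Trains a meta-classifier on the grid's out-of-fold probability matrix,
#' so the meta-level never sees in-fold (leaky) base predictions. The
#' default meta-algorithm is a random forest; any roster algorithm
#' (including the decision tree, for meta-classifier comparisons) can be
#' swapped in.
#'
#' @param grid a [train_grid()] result.
#' @param meta a [classifier_spec()] (default `classifier_spec("RF")`) or
#'   algorithm name.
#' @param labels training labels; defaults to the grid's own.
#' @return an object of class `m5c_stacked`.
#' @export
fit_meta <- function(grid, meta = classifier_spec("RF"), labels = grid$labels) {
  stopifnot(inherits(grid, "m5c_grid"))
  if (is.character(meta)) meta <- classifier_spec(meta)
  if (length(labels) != nrow(grid$oof)) {
    stop("labels (", length(labels), ") are misaligned with the OOF matrix (",
         nrow(grid$oof), " rows)")
  }
  meta_fit <- fit_classifier(meta, grid$oof, labels,
                             seed = cell_seed(grid$seed, length(grid$models) + 1L, 0L))
  structure(list(grid = grid, meta = meta_fit, meta_spec = meta),
            class = "m5c_stacked")
}

#' @export
print.m5c_stacked <- function(x, ...) {
  cat(sprintf("m5c_stacked: %s meta-classifier over %d base-model columns\n",
              x$meta_spec$algo, ncol(x$grid$oof)))
  invisible(x)
}

#' Stacked prediction on new windows
#'
#' @param model an [fit_meta()] result.
#' @param dataset an [m5c_dataset].
#' @param threshold decision threshold (default 0.5; probability >=
#'   threshold gives label 1).
#' @param base_matrix optionally, a precomputed [predict_grid()] matrix
#'   for `dataset` (shared with voting to avoid recomputation).
#' @return list with `probability`, `label`, and the base-model matrix
#'   `base` used.
#' @export
predict_stacked <- function(model, dataset, threshold = 0.5, base_matrix = NULL) {
  stopifnot(inherits(model, "m5c_stacked"))
  base <- base_matrix %||% predict_grid(model$grid, dataset)
  prob <- predict_classifier(model$meta, base)
  list(probability = prob,
       label = as.integer(prob >= threshold),
       base = base)
}

#' Voting ensemble over the base-model grid
#'
#' @param grid a [train_grid()] result.
#' @param mode `"soft"` (average the base probabilities) or `"hard"`
#'   (majority vote of base labels thresholded at `threshold`).
#' @param threshold probability threshold used to derive base votes in
#'   hard mode and the final label in soft mode (default 0.5).
#' @return an object of class `m5c_voting`.
#' @export
voting_model <- function(grid, mode = c("soft", "hard"), threshold = 0.5) {
  stopifnot(inherits(grid, "m5c_grid"))
  mode <- match.arg(mode)
  structure(list(grid = grid, mode = mode, threshold = threshold),
            class = "m5c_voting")
}

#' Voting prediction on new windows
#'
#' Soft mode returns the arithmetic mean of the base-model probabilities;
#' hard mode returns the fraction of base models voting positive
#' (probability >= threshold). The final label is 1 when the score is at
#' least 0.5 (a tied hard vote counts as positive).
#'
#' @param model a [voting_model()].
#' @param dataset an [m5c_dataset].
#' @param base_matrix optional precomputed [predict_grid()] matrix.
#' @return list with `score`, `label`, and the base matrix `base`.
#' @export
predict_voting <- function(model, dataset, base_matrix = NULL) {
  stopifnot(inherits(model, "m5c_voting"))
  base <- base_matrix %||% predict_grid(model$grid, dataset)
  score <- if (model$mode == "soft") {
    rowMeans(base)
  } else {
    rowMeans(base >= model$threshold)
  }
  list(score = score, label = as.integer(score >= 0.5), base = base)
}
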