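# The encoder x classifier grid of base models with leakage-free
# out-of-fold (OOF) meta-features. Every cell shares one stratified fold
# assignment so the OOF rows stay aligned across columns.

# stratified fold assignment: per class, shuffle then deal round-robin
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed %% .Machine$integer.max)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

cell_seed <- function(base, cell, fold) {
  (as.double(base) * 131L + 7919 * cell + 104729 * fold) %% 2147483647
}

#' Train the encoder-by-classifier grid of base models
#'
#' Fits one base model per (encoder, classifier) pair. For each pair, a
#' shared stratified `n_folds` split is used to produce out-of-fold
#' positive-class probabilities for every training record (each record is
#' predicted by a model whose training fold excluded it), and a final
#' model is refit on the full training set for prediction on new data.
#' The OOF matrix is the leakage-free meta-feature space consumed by the
#' stacking meta-classifier.
#'
#' @param dataset a labeled [m5c_dataset] with both classes present.
#' @param encoders named list of [encoder_spec()] (default: full roster).
#' @param classifiers named list of [classifier_spec()] (default: full
#'   roster of 11 algorithms, giving 121 grid cells).
#' @param n_folds number of stratified folds (default 5).
#' @param seed integer seed governing fold assignment and every model fit.
#' @return an object of class `m5c_grid` with elements `models` (named
#'   list of fitted cells), `oof` (n x cells matrix of out-of-fold
#'   probabilities, columns named `<algo>_<encoder>` in encoder-major
#'   order), `fold`, `labels`, `encoders`, `classifiers`, `n_folds`,
#'   `seed`, `window_length`.
#' @export
train_grid <- function(dataset, encoders = default_encoders(),
                       classifiers = default_classifiers(),
                       n_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "m5c_dataset"))
  y <- dataset$label
  if (anyNA(y)) stop("train_grid requires a fully labeled dataset")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > min(table(y))) {
    stop("n_folds must be >= 2 and <= the size of the smaller class")
  }
  encoders <- normalize_spec_list(encoders, encoder_spec, "name")
  classifiers <- normalize_spec_list(classifiers, classifier_spec, "algo")

  n <- length(y)
  fold <- stratified_folds(y, n_folds, seed)
  feats <- lapply(encoders, function(sp) encode_dataset(dataset, sp))

  col_names <- as.character(t(outer(names(encoders), tolower(names(classifiers)),
                                    function(e, c) paste0(c, "_", e))))
  oof <- matrix(NA_real_, nrow = n, ncol = length(col_names),
                dimnames = list(dataset$id, col_names))
  models <- vector("list", length(col_names))
  names(models) <- col_names

  ci <- 0L
  for (e in names(encoders)) {
    x <- feats[[e]]
    for (cname in names(classifiers)) {
      ci <- ci + 1L
      spec <- classifiers[[cname]]
      key <- paste0(tolower(spec$algo), "_", e)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit_f <- fit_classifier(spec, x[tr, , drop = FALSE], y[tr],
                                seed = cell_seed(seed, ci, f))
        oof[!tr, key] <- predict_classifier(fit_f, x[!tr, , drop = FALSE])
      }
      models[[key]] <- fit_classifier(spec, x, y, seed = cell_seed(seed, ci, 0L))
    }
  }
  structure(list(models = models, oof = oof, fold = fold, labels = y,
                 encoders = encoders, classifiers = classifiers,
                 n_folds = n_folds, seed = seed,
                 window_length = dataset$window_length),
            class = "m5c_grid")
}

normalize_spec_list <- function(specs, ctor, field) {
  if (inherits(specs, "encoder_spec") || inherits(specs, "classifier_spec")) {
    specs <- list(specs)
  }
  specs <- lapply(specs, function(s) if (is.character(s)) ctor(s) else s)
  nm <- vapply(specs, function(s) {
    v <- s[[field]]
    if (field == "algo") v else tolower(v)
  }, character(1L))
  if (anyDuplicated(nm)) stop("duplicate ", field, " in specification list")
  stats::setNames(specs, nm)
}

#' @export
print.m5c_grid <- function(x, ...) {
  cat(sprintf("m5c_grid: %d encoders x %d classifiers = %d base models (n = %d, %d folds)\n",
              length(x$encoders), length(x$classifiers),
              length(x$models), length(x$labels), x$n_folds))
  invisible(x)
}

#' Base-model probabilities on new data
#'
#' Column j of the result is the positive-class probability of the j-th
#' full-training base model, with the same `<algo>_<encoder>` column
#' schema and order as the grid's out-of-fold matrix.
#'
#' @param grid an [train_grid()] result.
#' @param dataset an [m5c_dataset] of windows with the grid's window length.
#' @return numeric matrix, rows = records, columns = grid cells.
#' @export
predict_grid <- function(grid, dataset) {
  stopifnot(inherits(grid, "m5c_grid"), inherits(dataset, "m5c_dataset"))
  if (dataset$window_length != grid$window_length) {
    stop("dataset window length ", dataset$window_length,
         " does not match the grid's (", grid$window_length, ")")
  }
  feats <- lapply(grid$encoders, function(sp) encode_dataset(dataset, sp))
  out <- matrix(NA_real_, nrow = length(dataset$id), ncol = length(grid$models),
                dimnames = list(dataset$id, names(grid$models)))
  for (e in names(grid$encoders)) {
    for (cname in names(grid$classifiers)) {
      key <- paste0(tolower(grid$classifiers[[cname]]$algo), "_", e)
      out[, key] <- predict_classifier(grid$models[[key]], feats[[e]])
    }
  }
  out
}

#' Cross-validated accuracy of every grid cell
#'
#' Accuracy of each base model's out-of-fold predictions (threshold 0.5)
#' against the training labels, arranged as an encoders x classifiers
#' table suitable for heatmap display.
#'
#' @param grid an [train_grid()] result.
#' @return numeric matrix, rows = encoders, columns = classifier algos.
#' @export
grid_accuracy <- function(grid) {
  stopifnot(inherits(grid, "m5c_grid"))
  enc <- names(grid$encoders)
  alg <- unname(vapply(grid$classifiers, function(s) s$algo, character(1L)))
  acc <- matrix(NA_real_, length(enc), length(alg),
                dimnames = list(enc, alg))
  for (e in enc) for (a in alg) {
    key <- paste0(tolower(a), "_", e)
    acc[e, a] <- mean((grid$oof[, key] >= 0.5) == grid$labels)
  }
  acc
}

#' Out-of-fold AUC of every grid column
#'
#' @param grid an [train_grid()] result.
#' @return named numeric vector of AUCs, one per `<algo>_<encoder>` column.
#' @export
grid_column_auc <- function(grid) {
  stopifnot(inherits(grid, "m5c_grid"))
  apply(grid$oof, 2L, function(p) roc_auc(grid$labels, p)$auc)
}

#' Draw an accuracy heatmap for a trained grid
#'
#' @param acc matrix from [grid_accuracy()] (or a trained grid).
#' @param main plot title.
#' @return the accuracy matrix, invisibly.
#' @export
plot_grid_accuracy <- function(acc, main = "Base-model CV accuracy") {
  if (inherits(acc, "m5c_grid")) acc <- grid_accuracy(acc)
  ne <- nrow(acc); nc <- ncol(acc)
  op <- graphics::par(mar = c(5, 7, 3, 2)); on.exit(graphics::par(op))
  graphics::image(seq_len(nc), seq_len(ne), t(acc),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "classifier", ylab = "", main = main)
  graphics::axis(1, at = seq_len(nc), labels = colnames(acc), las = 2)
  graphics::axis(2, at = seq_len(ne), labels = rownames(acc), las = 1)
  for (i in seq_len(ne)) for (j in seq_len(nc)) {
    graphics::text(j, i, sprintf("%.2f", acc[i, j]), cex = 0.7)
  }
  invisible(acc)
}
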