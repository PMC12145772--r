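# Model interpretation: Shapley-value feature attribution for base models
# and the meta-classifier, and a t-SNE embedding of the per-record
# base-model probability vectors.
#
# Two attribution backends are used. Gradient-boosted tree cells get the
# exact tree-path algorithm (TreeSHAP, on the margin/log-odds scale).
# Every other model gets Monte-Carlo permutation Shapley values on the
# probability scale: contributions are accumulated along random feature
# orderings between a background row and the explained row, which makes
# the per-sample attribution sum telescope exactly to
# f(x) - mean(f(background rows used)), i.e. local accuracy holds for
# both backends.

# permutation-sampling Shapley values
# predict_fun: matrix -> numeric; X: rows to explain; background: reference rows
shap_sampling <- function(predict_fun, X, background, n_perm = 32L, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(X); p <- ncol(X)
  phi <- matrix(0, n, p, dimnames = list(rownames(X), colnames(X)))
  z_rows <- sample.int(nrow(background), n_perm, replace = TRUE)
  base_acc <- 0
  for (b in seq_len(n_perm)) {
    z <- background[z_rows[b], ]
    perm <- sample.int(p)
    # big matrix of the p + 1 intermediate states for all n samples
    C <- matrix(z, nrow = n, ncol = p, byrow = TRUE)
    M <- matrix(NA_real_, n * (p + 1L), p)
    M[seq_len(n), ] <- C
    for (t in seq_len(p)) {
      C[, perm[t]] <- X[, perm[t]]
      M[t * n + seq_len(n), ] <- C
    }
    colnames(M) <- colnames(X)
    pred <- matrix(predict_fun(M), nrow = n)   # n x (p + 1)
    base_acc <- base_acc + pred[1L, 1L]        # all rows share state 0 = z
    for (t in seq_len(p)) {
      phi[, perm[t]] <- phi[, perm[t]] + (pred[, t + 1L] - pred[, t])
    }
  }
  list(values = phi / n_perm, base_value = base_acc / n_perm)
}

new_attribution <- function(values, base_value, output, backend) {
  mean_abs <- colMeans(abs(values))
  ranking <- data.frame(feature = colnames(values), mean_abs = mean_abs,
                        rank = rank(-mean_abs, ties.method = "first"),
                        row.names = NULL)
  ranking <- ranking[order(ranking$rank), ]
  structure(list(values = values, base_value = base_value,
                 feature_names = colnames(values), output = output,
                 ranking = ranking, backend = backend),
            class = "m5c_attribution")
}

#' @export
print.m5c_attribution <- function(x, n = 10L, ...) {
  cat(sprintf("m5c_attribution (%s backend): %d samples x %d features\n",
              x$backend, nrow(x$values), ncol(x$values)))
  cat("top features by mean |attribution|:\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.m5c_attribution <- function(x, n = 15L, ...) {
  top <- utils::head(x$ranking, n)
  op <- graphics::par(mar = c(5, 10, 3, 2)); on.exit(graphics::par(op))
  graphics::barplot(rev(top$mean_abs), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1, xlab = "mean |attribution|",
                    main = "Feature attribution")
  invisible(x)
}

# dispatch on the fitted cell: exact TreeSHAP for XGB, sampling otherwise
shap_for_fit <- function(fit, X, background, n_perm = 32L, seed = 1L) {
  if (fit$algo == "XGB") {
    dm <- xgboost::xgb.DMatrix(X, nthread = 1L)
    contrib <- predict(fit$model, dm, predcontrib = TRUE)
    p <- ncol(X)
    values <- contrib[, seq_len(p), drop = FALSE]
    colnames(values) <- colnames(X)
    output <- predict(fit$model, dm, outputmargin = TRUE)
    new_attribution(values, base_value = contrib[1L, p + 1L],
                    output = output, backend = "tree_exact")
  } else {
    res <- shap_sampling(function(m) predict_classifier(fit, m),
                         X, background, n_perm = n_perm, seed = seed)
    new_attribution(res$values, res$base_value,
                    output = predict_classifier(fit, X),
                    backend = "permutation_sampling")
  }
}

#' Shapley attribution for one base model of the grid
#'
#' Explains the predictions of the named (encoder, classifier) cell on
#' the given windows, over the encoder's named feature space (so the
#' ranking reads e.g. `ENAC_sw.22.G` or `Kmer_TAG`).
#'
#' @param grid a [train_grid()] result.
#' @param encoder encoder name of the cell.
#' @param classifier classifier algorithm of the cell.
#' @param dataset windows to explain.
#' @param sample_limit explain at most this many records (default 100).
#' @param background_size background rows for the sampling backend
#'   (default 100, drawn from the encoded dataset).
#' @param n_perm Monte-Carlo permutations for the sampling backend.
#' @param seed seed for subsampling and permutations.
#' @return an `m5c_attribution`: per-sample per-feature values,
#'   `base_value` (expected model output), per-sample model `output`, and
#'   the features ranked by mean absolute attribution. The exact tree
#'   backend works on the margin (log-odds) scale, the sampling backend
#'   on the probability scale; local accuracy (base value plus the row
#'   sum of attributions equals the model output) holds on the backend's
#'   scale.
#' @export
shap_base_model <- function(grid, encoder, classifier, dataset,
                            sample_limit = 100L, background_size = 100L,
                            n_perm = 32L, seed = 1L) {
  stopifnot(inherits(grid, "m5c_grid"))
  encoder <- normalize_encoder_name(encoder)
  key <- paste0(tolower(classifier), "_", encoder)
  fit <- grid$models[[key]]
  if (is.null(fit)) stop("unknown model key '", key, "'")
  X <- unclass(encode_dataset(dataset, grid$encoders[[encoder]]))
  set.seed(seed %% .Machine$integer.max)
  bg_idx <- sample.int(nrow(X), min(background_size, nrow(X)))
  keep <- seq_len(min(sample_limit, nrow(X)))
  shap_for_fit(fit, X[keep, , drop = FALSE], X[bg_idx, , drop = FALSE],
               n_perm = n_perm, seed = seed)
}

#' Shapley attribution for the stacking meta-classifier
#'
#' Explains the meta-classifier over its `<algo>_<encoder>` meta-feature
#' columns, showing which base models the stack leans on.
#'
#' @param stacked an [fit_meta()] result.
#' @param meta_features matrix of base-model probabilities to explain
#'   (defaults to the grid's out-of-fold matrix).
#' @param sample_limit,background_size,n_perm,seed as in
#'   [shap_base_model()].
#' @return an `m5c_attribution` over the base-model columns.
#' @export
shap_meta <- function(stacked, meta_features = NULL, sample_limit = 100L,
                      background_size = 100L, n_perm = 32L, seed = 1L) {
  stopifnot(inherits(stacked, "m5c_stacked"))
  X <- meta_features %||% stacked$grid$oof
  set.seed(seed %% .Machine$integer.max)
  bg_idx <- sample.int(nrow(X), min(background_size, nrow(X)))
  keep <- seq_len(min(sample_limit, nrow(X)))
  shap_for_fit(stacked$meta, X[keep, , drop = FALSE],
               X[bg_idx, , drop = FALSE], n_perm = n_perm, seed = seed)
}

# ---------------------------------------------------------------------------
# t-SNE (exact gradient; suitable for the desk-scale n used here)

# conditional similarity row with entropy calibrated to log(perplexity)
tsne_row_p <- function(d2, target_entropy, tol = 1e-5, max_tries = 50L) {
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (i in seq_len(max_tries)) {
    p <- exp(-d2 * beta)
    sum_p <- sum(p)
    if (sum_p == 0) { h <- 0; p <- rep(0, length(d2)) }
    else {
      h <- log(sum_p) + beta * sum(d2 * p) / sum_p
      p <- p / sum_p
    }
    diff <- h - target_entropy
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  p
}

#' t-SNE embedding of base-model probability vectors
#'
#' Embeds the per-record base-model probability vectors into 2-D by
#' t-distributed stochastic neighbor embedding (exact gradient descent on
#' the Kullback-Leibler divergence between the high- and low-dimensional
#' neighborhood distributions, with early exaggeration, momentum and
#' adaptive gains). Used to visualize whether the base models separate
#' methylated from unmethylated windows.
#'
#' @param prob_matrix numeric matrix (records x base models), e.g. from
#'   [predict_grid()] or a grid's out-of-fold matrix.
#' @param labels optional 0/1 labels stored for plotting.
#' @param perplexity neighborhood size parameter (default 30; requires
#'   `nrow(prob_matrix) > 3 * perplexity`).
#' @param seed seed for the random initial layout.
#' @param max_iter gradient-descent iterations (default 500).
#' @param eta learning rate.
#' @return object of class `m5c_tsne` with `coords` (n x 2, finite),
#'   `kl` (final divergence), `perplexity`, `seed`, `labels`.
#' @export
tsne_probabilities <- function(prob_matrix, labels = NULL, perplexity = 30,
                               seed = 1L, max_iter = 500L, eta = 200) {
  X <- as.matrix(prob_matrix)
  n <- nrow(X)
  if (n <= 3 * perplexity) {
    stop("need n > 3 * perplexity; with n = ", n,
         " try perplexity <= ", floor((n - 1) / 3))
  }
  if (!is.null(labels) && length(labels) != n) stop("labels misaligned")
  set.seed(seed %% .Machine$integer.max)

  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, -i] <- tsne_row_p(D2[i, -i], log(perplexity))
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  update <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration <- 4; exag_iter <- 100L
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= exag_iter) P * exaggeration else P
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    momentum <- if (iter <= 250L) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(update),
                               gains + 0.2, gains * 0.8))
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  sqy <- rowSums(Y^2)
  num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
  diag(num) <- 0
  Q <- pmax(num / sum(num), 1e-12)
  kl <- sum(P * log(P / Q))
  structure(list(coords = Y, kl = kl, perplexity = perplexity,
                 seed = seed, labels = labels),
            class = "m5c_tsne")
}

#' @export
print.m5c_tsne <- function(x, ...) {
  cat(sprintf("m5c_tsne: %d points, perplexity %.0f, KL divergence %.4f\n",
              nrow(x$coords), x$perplexity, x$kl))
  invisible(x)
}

#' @export
plot.m5c_tsne <- function(x, ...) {
  col <- if (is.null(x$labels)) "grey30" else ifelse(x$labels == 1, "#1b9e77", "#d95f02")
  graphics::plot(x$coords, col = col, pch = 19, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "Base-model probability embedding")
  if (!is.null(x$labels)) {
    graphics::legend("topright", legend = c("m5C", "non-m5C"),
                     col = c("#1b9e77", "#d95f02"), pch = 19, bty = "n")
  }
  invisible(x)
}
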