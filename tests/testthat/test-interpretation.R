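# Shapley attribution (exact tree backend and permutation sampling) and
# the t-SNE embedding of base-model probabilities.

interp_grid <- function(n = 150, seed = 71) {
  ds <- generate_dataset(n / 2, n / 2,
                         motif = motif_model(effect_size = "strong"),
                         seed = seed)
  list(ds = ds,
       grid = train_grid(ds, encoders = c("nac", "ncp"),
                         classifiers = c("XGB", "RF"), seed = seed))
}

test_that("the exact tree backend satisfies local accuracy", {
  fx <- interp_grid()
  att <- shap_base_model(fx$grid, "ncp", "XGB", fx$ds, sample_limit = 50)
  expect_identical(att$backend, "tree_exact")
  expect_identical(dim(att$values), c(50L, 123L))
  residual <- att$base_value + rowSums(att$values) - att$output
  expect_lt(max(abs(residual)), 1e-5)
})

test_that("the sampling backend satisfies local accuracy by telescoping", {
  fx <- interp_grid(n = 80)
  att <- shap_base_model(fx$grid, "nac", "RF", fx$ds, sample_limit = 25,
                         n_perm = 12, seed = 5)
  expect_identical(att$backend, "permutation_sampling")
  residual <- att$base_value + rowSums(att$values) - att$output
  expect_lt(max(abs(residual)), 1e-8)
})

test_that("constant features receive zero attribution from the exact backend", {
  fx <- interp_grid()
  att <- shap_base_model(fx$grid, "ncp", "XGB", fx$ds, sample_limit = 30)
  # the fixed center cytosine makes positions 21's NCP triple constant
  const_cols <- grep("NCP_21_", colnames(att$values))
  expect_length(const_cols, 3L)
  expect_true(all(att$values[, const_cols] == 0))
})

test_that("a planted informative feature ranks first for both backends", {
  set.seed(91)
  n <- 200
  x <- cbind(noise1 = rnorm(n), signal = rnorm(n), noise2 = rnorm(n),
             const = rep(1, n))
  y <- as.integer(x[, "signal"] > 0)
  for (algo in c("XGB", "RF")) {
    fit <- methylstack:::fit_classifier(classifier_spec(algo), x, y, seed = 3)
    att <- methylstack:::shap_for_fit(fit, x[1:40, ], x, n_perm = 16, seed = 4)
    expect_identical(att$ranking$feature[1], "signal", info = algo)
  }
})

test_that("an oracle meta-feature column dominates the meta attribution", {
  fx <- interp_grid(n = 120)
  g <- fx$grid
  g$oof[, "rf_nac"] <- g$labels          # plant the oracle column
  st <- fit_meta(g)
  att <- shap_meta(st, sample_limit = 50, n_perm = 16, seed = 6)
  expect_identical(att$ranking$feature[1], "rf_nac")
  expect_identical(dim(att$values), c(50L, 4L))
})

test_that("attribution rankings are reproducible under a fixed seed", {
  fx <- interp_grid(n = 80)
  a1 <- shap_base_model(fx$grid, "nac", "RF", fx$ds, sample_limit = 20,
                        n_perm = 8, seed = 11)
  a2 <- shap_base_model(fx$grid, "nac", "RF", fx$ds, sample_limit = 20,
                        n_perm = 8, seed = 11)
  expect_identical(a1$ranking, a2$ranking)
  expect_equal(a1$values, a2$values)
})

test_that("unknown grid cells are rejected", {
  fx <- interp_grid(n = 60)
  expect_error(shap_base_model(fx$grid, "nac", "SVM", fx$ds),
               "unknown model key")
})

test_that("t-SNE preserves the separability of well-separated clusters", {
  set.seed(131)
  n <- 210
  y <- rep(c(1L, 0L), length.out = n)
  probs <- matrix(0, n, 6)
  probs[y == 1, ] <- runif(sum(y == 1) * 6, 0.85, 1)
  probs[y == 0, ] <- runif(sum(y == 0) * 6, 0, 0.15)
  emb <- tsne_probabilities(probs, labels = y, perplexity = 25, seed = 2,
                            max_iter = 350)
  expect_identical(dim(emb$coords), c(as.integer(n), 2L))
  expect_true(all(is.finite(emb$coords)))
  fit <- MASS::lda(emb$coords, grouping = factor(y))
  acc <- mean(predict(fit, emb$coords)$class == factor(y))
  expect_gte(acc, 0.95)
})

test_that("duplicated inputs land on near-coincident embedding points", {
  # classifier-probability-like input: two clusters near 0 and 1
  set.seed(132)
  n <- 120
  y <- rep(c(1, 0), length.out = n)
  probs <- matrix(0, n, 4)
  probs[y == 1, ] <- runif(sum(y == 1) * 4, 0.8, 1)
  probs[y == 0, ] <- runif(sum(y == 0) * 4, 0, 0.2)
  probs[n, ] <- probs[1, ]               # exact duplicate
  emb <- tsne_probabilities(probs, perplexity = 15, seed = 3, max_iter = 500)
  d_dup <- sqrt(sum((emb$coords[1, ] - emb$coords[n, ])^2))
  diameter <- max(stats::dist(emb$coords))
  expect_lt(d_dup, 0.01 * diameter)
})

test_that("embeddings are reproducible and perplexity limits are enforced", {
  set.seed(133)
  probs <- matrix(runif(100 * 3), 100, 3)
  e1 <- tsne_probabilities(probs, perplexity = 10, seed = 4, max_iter = 100)
  e2 <- tsne_probabilities(probs, perplexity = 10, seed = 4, max_iter = 100)
  expect_identical(e1$coords, e2$coords)
  expect_true(is.finite(e1$kl))
  expect_error(tsne_probabilities(probs, perplexity = 40),
               "perplexity <= 33")
})
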