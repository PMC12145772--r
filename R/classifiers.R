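# Base-classifier registry. Every algorithm is wrapped behind a uniform
# fit/predict-probability interface so the grid, the stacker and the voter
# treat all cells identically. Feature standardization (training-set mean
# and standard deviation) is applied for margin, neighbor, linear and
# network classifiers; tree ensembles and the scale-invariant LDA / naive
# Bayes consume raw features. Zero-variance columns (e.g. the fixed center
# cytosine in one-hot encoders) are dropped where the algorithm cannot
# tolerate them.

CLASSIFIER_ALGOS <- c("XGB", "ADA", "SVM", "ET", "KNN", "LR",
                      "RF", "MLP", "NB", "DT", "LDA")

SCALED_ALGOS <- c("SVM", "KNN", "LR", "MLP")
DROP_CONST_ALGOS <- c("NB", "LDA")

classifier_defaults <- function(algo) {
  switch(algo,
    XGB = list(nrounds = 100L, max_depth = 6L, eta = 0.3, nthread = 1L),
    ADA = list(n_rounds = 50L, stump_depth = 1L),
    SVM = list(kernel = "radial", cost = 1),
    ET  = list(num.trees = 100L),
    KNN = list(k = 5L),
    LR  = list(lambda = NULL),          # NULL -> 1/n ridge
    RF  = list(ntree = 100L),
    MLP = list(size = 8L, decay = 0.01, maxit = 200L),
    NB  = list(),
    DT  = list(cp = 0.01),
    LDA = list(),
    stop("unknown classifier algorithm '", algo, "'")
  )
}

#' Classifier specification
#'
#' @param algo one of `"XGB"` (gradient-boosted trees), `"ADA"`
#'   (AdaBoost.M1 over decision stumps), `"SVM"` (RBF support vector
#'   machine with cross-validated Platt probabilities), `"ET"` (extremely
#'   randomized trees), `"KNN"`, `"LR"` (ridge-regularized logistic
#'   regression), `"RF"` (random forest), `"MLP"` (single-hidden-layer
#'   neural network), `"NB"` (Gaussian naive Bayes), `"DT"` (CART decision
#'   tree), `"LDA"` (linear discriminant analysis).
#' @param ... hyperparameters overriding the documented defaults.
#' @param seed integer seed used when fitting this classifier.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(algo, ..., seed = 1L) {
  algo <- toupper(algo)
  if (!algo %in% CLASSIFIER_ALGOS) {
    stop("unknown classifier '", algo, "'; available: ",
         paste(CLASSIFIER_ALGOS, collapse = ", "))
  }
  defaults <- classifier_defaults(algo)
  params <- utils::modifyList(defaults, list(...))
  structure(list(algo = algo, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("classifier_spec:", x$algo, "\n")
  invisible(x)
}

#' Default classifier roster
#'
#' Eleven algorithm families spanning gradient boosting, bagging, margin,
#' neighbor, linear, network and probabilistic classifiers.
#'
#' @param seed base seed recorded in each spec.
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function(seed = 1L) {
  stats::setNames(lapply(CLASSIFIER_ALGOS, classifier_spec, seed = seed),
                  CLASSIFIER_ALGOS)
}

# ---------------------------------------------------------------------------
# AdaBoost.M1 over rpart stumps. Probability via the logistic link on the
# ensemble margin F(x) = sum_m alpha_m h_m(x), h_m in {-1, +1}:
# p(y = 1 | x) = 1 / (1 + exp(-2 F(x))).

fit_adaboost <- function(x, y, n_rounds = 50L, stump_depth = 1L) {
  n <- length(y)
  w <- rep(1 / n, n)
  ypm <- ifelse(y == 1L, 1, -1)
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x, check.names = FALSE)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = stump_depth,
                                                       cp = -1, minsplit = 2L,
                                                       xval = 0L))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != ypm))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
    if (err >= 0.5) break                 # weak learner no better than chance
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
    if (err < 1e-9) break                 # perfect stump, margin saturates
  }
  structure(list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)]),
            class = "adaboost_fit")
}

predict_adaboost <- function(fit, x) {
  df <- as.data.frame(x, check.names = FALSE)
  f <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    f <- f + fit$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))
}

# ---------------------------------------------------------------------------

# fit one classifier; x numeric matrix, y integer 0/1
fit_classifier <- function(spec, x, y, seed = spec$seed) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  p <- spec$params
  algo <- spec$algo
  set.seed(seed %% .Machine$integer.max)

  center <- NULL; scale <- NULL; keep <- NULL
  if (algo %in% SCALED_ALGOS) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale < 1e-12] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  if (algo %in% DROP_CONST_ALGOS) {
    # Gaussian NB and LDA require non-degenerate within-class variance
    sd0 <- apply(x[y == 0L, , drop = FALSE], 2L, stats::sd)
    sd1 <- apply(x[y == 1L, , drop = FALSE], 2L, stats::sd)
    keep <- which(sd0 > 1e-10 & sd1 > 1e-10)
    if (length(keep) == 0L) stop("all features degenerate within classes; cannot fit ", algo)
    x <- x[, keep, drop = FALSE]
  }

  model <- switch(algo,
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, nthread = p$nthread,
                    seed = seed %% .Machine$integer.max),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = p$nthread),
      nrounds = p$nrounds, verbose = 0),
    ADA = fit_adaboost(x, y, n_rounds = p$n_rounds, stump_depth = p$stump_depth),
    SVM = e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = p$kernel,
                     cost = p$cost, probability = TRUE, scale = FALSE),
    ET  = ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                         num.trees = p$num.trees, splitrule = "extratrees",
                         replace = FALSE, sample.fraction = 1,
                         probability = TRUE, num.threads = 1L,
                         seed = seed %% .Machine$integer.max),
    KNN = list(train = x, y = y, k = p$k),
    LR  = {
      lam <- if (is.null(p$lambda)) 1 / nrow(x) else p$lambda
      if (ncol(x) < 2L) {               # glmnet needs >= 2 columns
        x <- cbind(x, .zero = 0)
      }
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE)
    },
    RF  = randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                     ntree = p$ntree),
    MLP = nnet::nnet(x, y, size = p$size, decay = p$decay, maxit = p$maxit,
                     entropy = TRUE, trace = FALSE,
                     MaxNWts = (ncol(x) + 1L) * p$size + p$size + 1L + 10L),
    NB  = e1071::naiveBayes(x, factor(y, levels = c(0L, 1L))),
    DT  = rpart::rpart(.y ~ ., method = "class",
                       data = data.frame(.y = factor(y, levels = c(0L, 1L)), x,
                                         check.names = FALSE),
                       control = rpart::rpart.control(cp = p$cp, xval = 0L)),
    LDA = suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0L, 1L))))
  )
  structure(list(algo = algo, model = model, spec = spec,
                 center = center, scale = scale, keep = keep,
                 n_features = length(center) %||% ncol(x)),
            class = "m5c_classifier_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# positive-class probability on new data
predict_classifier <- function(fit, x) {
  stopifnot(inherits(fit, "m5c_classifier_fit"))
  if (!is.null(fit$center)) {
    x <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  }
  if (!is.null(fit$keep)) x <- x[, fit$keep, drop = FALSE]
  m <- fit$model
  prob <- switch(fit$algo,
    XGB = predict(m, xgboost::xgb.DMatrix(x, nthread = 1L)),
    ADA = predict_adaboost(m, x),
    SVM = {
      pr <- attr(predict(m, x, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    ET  = predict(m, data = x, num.threads = 1L)$predictions[, "1"],
    KNN = {
      cl <- class::knn(m$train, x, cl = factor(m$y, levels = c(0L, 1L)),
                       k = m$k, prob = TRUE, use.all = TRUE)
      pw <- attr(cl, "prob")             # proportion of votes for winner
      ifelse(cl == "1", pw, 1 - pw)
    },
    LR  = {
      if (ncol(x) < 2L) x <- cbind(x, .zero = 0)
      as.numeric(predict(m, x, type = "response"))
    },
    RF  = predict(m, x, type = "prob")[, "1"],
    MLP = as.numeric(predict(m, x)),
    NB  = predict(m, x, type = "raw")[, "1"],
    DT  = predict(m, as.data.frame(x, check.names = FALSE), type = "prob")[, "1"],
    LDA = predict(m, x)$posterior[, "1"]
  )
  pmin(pmax(as.numeric(prob), 0), 1)
}
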