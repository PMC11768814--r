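`%||%` <- function(a, b) if (is.null(a)) b else a

#' Algorithms available to the classification harness
#' @return Character vector of algorithm codes.
#' @export
algorithm_roster <- function() {
  c("rf", "xgboost", "cnb", "gbm", "knn", "lr", "ann", "svm")
}

#' Train/test split
#'
#' Deterministic seeded split with the floor convention
#' (`n_train = floor(ratio * n)`); when stratified, per-class training
#' counts are allocated by largest remainder so class balance is
#' preserved even for small classes.
#'
#' @param y Label vector (used for stratification and length).
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify by label (default TRUE).
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(y, ratio = 0.7, seed = 1, stratify = TRUE) {
  n <- length(y)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  n_train <- floor(ratio * n)
  if (n_train == 0 || n_train == n) stop("split leaves an empty set")
  if (!stratify) {
    train <- with_seed(seed, sample(n, n_train))
    return(list(train = sort(train), test = sort(setdiff(seq_len(n), train))))
  }
  y <- if (is.factor(y)) y else factor(y)
  if (any(table(y) == 0)) stop("class with 0 members under stratification")
  raw <- ratio * as.vector(table(y))
  k <- floor(raw)
  left <- n_train - sum(k)
  if (left > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[add] <- k[add] + 1
  }
  train <- with_seed(seed, {
    unlist(lapply(seq_along(levels(y)), function(i) {
      idx <- which(y == levels(y)[i])
      if (k[i] > length(idx)) stop("class too small for requested ratio")
      sample(idx, k[i])
    }))
  })
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
}

# z-score scaler fitted on training data only
fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}
apply_scaler <- function(X, s) {
  sweep(sweep(X, 2, s$center, "-"), 2, s$scale, "/")
}

#' Train a regulatory-status classifier
#'
#' One fitting surface over eight algorithm families: random forest
#' (`rf`), two gradient-boosting configurations (`xgboost` with its
#' regularized defaults and `gbm` with classic unregularized boosting
#' settings), complement naive Bayes (`cnb`), k-nearest neighbours
#' (`knn`), multinomial logistic regression (`lr`), a single-hidden-layer
#' perceptron (`ann`), and an RBF support vector machine (`svm`).
#' Features are z-scored internally (fit on the training data only) for
#' the scale-sensitive families knn/svm/lr/ann. With `tune = TRUE` a small
#' documented grid per family is selected by stratified k-fold
#' cross-validation on the training set.
#'
#' @param algorithm One of [algorithm_roster()].
#' @param X Complete numeric feature matrix (molecules x descriptors).
#' @param y Class labels.
#' @param hyperparameters Named list overriding the family defaults
#'   (`n_trees`, `k`, `cost`, `eta`, `max_depth`, `nrounds`, `decay`,
#'   `size`, `alpha`, `maxit`).
#' @param seed Integer seed; fixing it makes predictions reproducible.
#' @param tune Select hyperparameters by training-set cross-validation
#'   over [default_grid()].
#' @return Object of class `ops_model` supporting [predict()].
#' @export
train_classifier <- function(algorithm, X, y, hyperparameters = list(),
                             seed = 1, tune = FALSE) {
  algorithm <- match.arg(algorithm, algorithm_roster())
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  validate_axis_names(colnames(X), "descriptor")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  stopifnot(nrow(X) == length(y))

  if (tune && length(hyperparameters) == 0) {
    hyperparameters <- cv_select(algorithm, X, y, seed)
  }
  hp <- hyperparameters

  needs_scaling <- algorithm %in% c("knn", "svm", "lr", "ann")
  scaler <- if (needs_scaling) fit_scaler(X) else NULL
  Xs <- if (needs_scaling) apply_scaler(X, scaler) else X

  fit <- with_seed(seed, switch(algorithm,
    rf = randomForest::randomForest(x = as.data.frame(Xs), y = y,
                                    ntree = hp$n_trees %||% 500),
    xgboost = fit_xgb(Xs, y, eta = hp$eta %||% 0.3,
                      max_depth = hp$max_depth %||% 6,
                      nrounds = hp$nrounds %||% 100,
                      lambda = 1, seed = seed),
    gbm = fit_xgb(Xs, y, eta = hp$eta %||% 0.1,
                  max_depth = hp$max_depth %||% 3,
                  nrounds = hp$nrounds %||% 100,
                  lambda = 0, seed = seed),
    cnb = fit_cnb(Xs, y, alpha = hp$alpha %||% 1),
    knn = list(train = Xs, y = y, k = hp$k %||% 5),
    lr = nnet::multinom(y ~ ., data = data.frame(y = y, Xs,
                                                 check.names = FALSE),
                        trace = FALSE, maxit = hp$maxit %||% 300,
                        decay = hp$decay %||% 1e-4, MaxNWts = 1e5),
    ann = nnet::nnet(x = Xs, y = nnet::class.ind(y),
                     size = hp$size %||% 64, softmax = TRUE,
                     decay = hp$decay %||% 0.01,
                     maxit = hp$maxit %||% 200,
                     MaxNWts = 1e6, trace = FALSE),
    svm = e1071::svm(x = Xs, y = y, kernel = "radial", scale = FALSE,
                     cost = hp$cost %||% 1)
  ))
  structure(list(algorithm = algorithm, fit = fit,
                 feature_names = colnames(X), classes = levels(y),
                 scaler = scaler, hyperparameters = hp, seed = seed),
            class = "ops_model")
}

fit_xgb <- function(X, y, eta, max_depth, nrounds, lambda, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  params <- list(objective = "multi:softprob", num_class = nlevels(y),
                 eta = eta, max_depth = max_depth, lambda = lambda,
                 alpha = 0, subsample = 1, colsample_bytree = 1,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

# Complement naive Bayes (Rennie-style) on [0,1] min-max-scaled features:
# class weights are log complement-class feature totals, length-normalized;
# the predicted class minimizes the weighted feature sum.
fit_cnb <- function(X, y, alpha = 1) {
  rng_min <- apply(X, 2, min)
  rng_max <- apply(X, 2, max)
  span <- pmax(rng_max - rng_min, .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, rng_min, "-"), 2, span, "/")
  W <- sapply(levels(y), function(cl) {
    comp <- Xs[y != cl, , drop = FALSE]
    njc <- alpha + colSums(comp)
    w <- log(njc / sum(njc))
    w / sum(abs(w))
  })
  list(weights = W, rng_min = rng_min, span = span, classes = levels(y))
}

predict_cnb <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$rng_min, "-"), 2, fit$span, "/")
  Xs[Xs < 0] <- 0; Xs[Xs > 1] <- 1
  scores <- Xs %*% fit$weights
  fit$classes[apply(scores, 1, which.min)]
}

#' A small documented hyperparameter grid per algorithm family
#' @param algorithm One of [algorithm_roster()].
#' @return List of candidate hyperparameter lists.
#' @export
default_grid <- function(algorithm) {
  algorithm <- match.arg(algorithm, algorithm_roster())
  expand <- function(...) {
    g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  switch(algorithm,
    rf = expand(n_trees = c(100, 500)),
    xgboost = expand(nrounds = c(50, 100), max_depth = c(3, 6)),
    gbm = expand(nrounds = c(50, 100)),
    cnb = expand(alpha = c(0.5, 1)),
    knn = expand(k = c(3, 5, 7)),
    lr = expand(decay = c(1e-4, 1e-2)),
    ann = expand(decay = c(1e-3, 1e-2)),
    svm = expand(cost = c(1, 10))
  )
}

# stratified k-fold CV over default_grid; returns the winning candidate
cv_select <- function(algorithm, X, y, seed, folds = 3) {
  grid <- default_grid(algorithm)
  if (length(grid) < 2) return(grid[[1]])
  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  acc <- vapply(grid, function(hp) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < nlevels(y)) return(NA_real_)
      m <- train_classifier(algorithm, X[tr, , drop = FALSE], y[tr],
                            hyperparameters = hp, seed = seed)
      mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(acc)]]
}

#' @export
predict.ops_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  if (!is.null(object$scaler)) X <- apply_scaler(X, object$scaler)
  out <- switch(object$algorithm,
    rf = as.character(stats::predict(object$fit, as.data.frame(X))),
    xgboost = ,
    gbm = {
      pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(X))
      pr <- matrix(pr, ncol = length(object$classes), byrow = is.null(dim(pr)))
      object$classes[max.col(pr, ties.method = "first")]
    },
    cnb = predict_cnb(object$fit, X),
    knn = as.character(with_seed(object$seed,
      class::knn(object$fit$train, X, object$fit$y, k = object$fit$k))),
    lr = as.character(stats::predict(object$fit,
      newdata = data.frame(X, check.names = FALSE))),
    ann = {
      pr <- stats::predict(object$fit, X)
      object$classes[max.col(pr, ties.method = "first")]
    },
    svm = as.character(stats::predict(object$fit, X))
  )
  factor(out, levels = object$classes)
}

#' @export
print.ops_model <- function(x, ...) {
  cat(sprintf("<ops_model> %s over %d features, classes: %s\n",
              x$algorithm, length(x$feature_names),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Confusion matrix and metric suite
#'
#' Builds the K x K confusion matrix (rows = predicted, columns = true)
#' and the metric suite: accuracy = trace / total; precision, recall and
#' F1 are per-class one-vs-rest values combined by support-weighted
#' average (classes with a zero denominator contribute 0). On a complete
#' test set the support-weighted recall algebraically equals accuracy.
#'
#' @param pred,truth Equal-length label vectors.
#' @param class_order Ordered class labels; any label outside it is an
#'   error. Default: union of observed levels.
#' @return List of class `ops_evaluation` with elements `confusion`
#'   (matrix) and `metrics` (accuracy, precision, recall, f1, averaging,
#'   per_class data frame).
#' @export
evaluate <- function(pred, truth, class_order = NULL) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("pred and truth must have equal positive length", call. = FALSE)
  }
  if (is.null(class_order)) class_order <- sort(unique(c(pred, truth)))
  bad <- setdiff(unique(c(pred, truth)), class_order)
  if (length(bad)) stop("label(s) outside class_order: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  conf <- table(predicted = factor(pred, class_order),
                true = factor(truth, class_order))
  conf <- unclass(conf)
  total <- sum(conf)
  tp <- diag(conf)
  pred_tot <- rowSums(conf)
  true_tot <- colSums(conf)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision_k <- safe_div(tp, pred_tot)
  recall_k <- safe_div(tp, true_tot)
  f1_k <- safe_div(2 * precision_k * recall_k, precision_k + recall_k)
  w <- true_tot / total
  per_class <- data.frame(class = class_order, support = as.integer(true_tot),
                          precision = unname(precision_k),
                          recall = unname(recall_k), f1 = unname(f1_k))
  metrics <- list(accuracy = sum(tp) / total,
                  precision = sum(w * precision_k),
                  recall = sum(w * recall_k),
                  f1 = sum(w * f1_k),
                  averaging = "weighted",
                  per_class = per_class)
  structure(list(confusion = conf, metrics = metrics),
            class = "ops_evaluation")
}

#' @export
print.ops_evaluation <- function(x, ...) {
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (weighted)\n",
              m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

#' External validation on an untouched label set
#'
#' Scores a fitted model against an external reference list (e.g. another
#' jurisdiction's management list) with the same metric suite as the
#' internal test set.
#'
#' @param model An `ops_model`.
#' @param X_ext Feature matrix for the external molecules.
#' @param y_ext External labels, within the model's class space.
#' @return An `ops_evaluation`.
#' @export
external_validate <- function(model, X_ext, y_ext) {
  if (NROW(X_ext) == 0) stop("empty external set", call. = FALSE)
  pred <- predict(model, X_ext)
  evaluate(pred, y_ext, class_order = model$classes)
}

#' Predict unlabeled molecules and tally the classes
#'
#' @param model A fitted 3-class y1 `ops_model`.
#' @param X_unlabeled Feature matrix.
#' @return List with `predictions` (factor) and `counts` (named integer
#'   vector over the model's classes, summing to `nrow(X_unlabeled)`).
#' @export
apply_and_tally <- function(model, X_unlabeled) {
  if (NROW(X_unlabeled) == 0) {
    counts <- stats::setNames(integer(length(model$classes)), model$classes)
    return(list(predictions = factor(character(), levels = model$classes),
                counts = counts))
  }
  pred <- predict(model, X_unlabeled)
  list(predictions = pred, counts = tally_labels(pred, model$classes))
}

#' Tally labels over a fixed class order
#' @param labels Label vector.
#' @param class_order Class order for the counts (default y1 levels).
#' @return Named integer vector of counts.
#' @export
tally_labels <- function(labels, class_order = regulatory_levels("y1")) {
  bad <- setdiff(unique(as.character(labels)), class_order)
  if (length(bad)) stop("label(s) outside class_order: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(factor(as.character(labels), levels = class_order))
  stats::setNames(as.integer(tab), class_order)
}
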