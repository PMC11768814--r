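#' Drop descriptors unusable for modelling
#'
#' Removes every descriptor column that contains at least one missing
#' value or has zero variance (constant). Molecule rows are untouched.
#' This is the missing-value handling step preceding redundancy pruning:
#' descriptor software fails on some structures, and column-wise deletion
#' is auditable where imputation is not.
#'
#' @param X Descriptor matrix.
#' @return The reduced matrix, with attribute `removed` naming dropped
#'   columns.
#' @export
drop_unusable_descriptors <- function(X) {
  has_na <- apply(X, 2, anyNA)
  const <- !has_na & apply(X, 2, function(v) max(v) == min(v))
  keep <- !(has_na | const)
  if (!any(keep)) stop("no usable descriptors", call. = FALSE)
  out <- X[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(X)[!keep]
  out
}

#' Pearson redundancy pruning
#'
#' Greedy scan in a deterministic order (descending column variance, ties
#' by name): a descriptor is retained iff its absolute Pearson correlation
#' with every previously retained descriptor is below `threshold`. Keeping
#' the most spread descriptor of each correlated block makes the result
#' reproducible without an arbitrary input ordering.
#'
#' @param X Complete descriptor matrix (run [drop_unusable_descriptors()]
#'   first).
#' @param threshold Absolute-correlation cutoff in (0, 1\].
#' @return Character vector of retained descriptor names, in scan order.
#' @export
pearson_prune <- function(X, threshold = 0.95) {
  if (anyNA(X)) stop("missing values present; run drop_unusable_descriptors first",
                     call. = FALSE)
  if (nrow(X) < 2) stop("need >= 2 molecules for correlations", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  v <- apply(X, 2, stats::var)
  ord <- order(-v, colnames(X))
  retained <- integer()
  for (j in ord) {
    if (length(retained) == 0L) { retained <- j; next }
    r <- suppressWarnings(abs(stats::cor(X[, j], X[, retained, drop = FALSE])))
    r[is.na(r)] <- 0  # constant column: no linear redundancy
    if (all(r < threshold)) retained <- c(retained, j)
  }
  colnames(X)[retained]
}

#' Random-forest importance ranking
#'
#' Fits a seeded random forest and reports each descriptor's impurity
#' (Gini) importance, normalized to a share of the total, sorted
#' descending with ties broken by name.
#'
#' @param X Complete descriptor matrix.
#' @param y Class labels (factor or coercible), >= 2 classes.
#' @param seed Integer seed for the forest.
#' @param n_trees Number of trees.
#' @return Data frame of class `importance_table` with columns
#'   `descriptor` and `importance` (shares summing to 1).
#' @export
importance_rank <- function(X, y, seed = 1, n_trees = 500) {
  if (anyNA(X)) stop("missing values present", call. = FALSE)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes", call. = FALSE)
  y <- droplevels(y)
  fit <- with_seed(seed, randomForest::randomForest(
    x = as.data.frame(X), y = y, ntree = n_trees, importance = FALSE))
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  share <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  out <- data.frame(descriptor = colnames(X), importance = unname(share))
  out <- out[order(-out$importance, out$descriptor), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Min-max relative importance
#'
#' Adds `relative_importance = (importance - min) / (max - min)`, the
#' scale on which importance rankings are reported: the top descriptor
#' maps to 1, the bottom to 0.
#'
#' @param tbl Data frame with an `importance` column (>= 2 rows).
#' @return `tbl` with a `relative_importance` column appended/replaced.
#' @export
relative_importance <- function(tbl) {
  if (nrow(tbl) < 2) stop("need >= 2 rows", call. = FALSE)
  rng <- range(tbl$importance)
  if (diff(rng) == 0) stop("degenerate importance range", call. = FALSE)
  tbl$relative_importance <- (tbl$importance - rng[1]) / diff(rng)
  tbl
}
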