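#' Orientation-aware min-max normalization
#'
#' Rescales every indicator to \[0, 1\] so that larger always means more
#' toxic: benefit-oriented columns (probability endpoints, BCF) map
#' through `(x - min) / (max - min)`; cost-oriented columns (IGC50,
#' LC50DM, LC50FM, where a lower concentration is more potent) map
#' through `(max - x) / (max - min)`. Constant columns map to 0.5 with a
#' warning -- they carry no ranking information and receive zero entropy
#' weight downstream, so the value is inert.
#'
#' @param T_ A [toxicity_matrix()].
#' @return Numeric matrix in \[0, 1\] (entities x indicators).
#' @export
orient_normalize <- function(T_) {
  stopifnot(inherits(T_, "toxicity_matrix"))
  V <- T_$values
  if (anyNA(V)) stop("missing values in toxicity matrix", call. = FALSE)
  prob_cols <- intersect(colnames(V), probability_indicator_names())
  if (any(V[, prob_cols, drop = FALSE] < 0)) {
    stop("negative probability indicator", call. = FALSE)
  }
  R <- V
  constant <- character()
  for (j in colnames(V)) {
    rng <- range(V[, j])
    if (diff(rng) == 0) {
      R[, j] <- 0.5
      constant <- c(constant, j)
      next
    }
    R[, j] <- if (T_$orientation[[j]] == "cost") {
      (rng[2] - V[, j]) / diff(rng)
    } else {
      (V[, j] - rng[1]) / diff(rng)
    }
  }
  if (length(constant)) {
    warning("constant indicator(s) mapped to 0.5: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  R
}

#' Entropy weights for toxicity indicators
#'
#' Objective indicator weights from Shannon information entropy of the
#' column-wise share distribution: `p_ij = r_ij / sum_i r_ij` (with
#' `0 * log 0 := 0`), `e_j = -(1 / log n) * sum_i p_ij log p_ij`, and
#' `w_j = (1 - e_j) / sum_k (1 - e_k)`. Indicators whose values vary more
#' across entities have lower entropy and receive larger weights; a
#' constant column has entropy 1 and weight 0.
#'
#' @param R Normalized matrix from [orient_normalize()] (values >= 0,
#'   >= 2 entities).
#' @return Data frame of class `entropy_weights` with columns `indicator`,
#'   `entropy`, `weight` (weights summing to 1).
#' @export
entropy_weights <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) < 2) stop("need >= 2 entities", call. = FALSE)
  if (any(R < 0)) stop("normalized values must be >= 0", call. = FALSE)
  n <- nrow(R)
  e <- apply(R, 2, function(col) {
    tot <- sum(col)
    if (tot == 0 || max(col) == min(col)) return(1)  # constant: no information
    p <- col / tot
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(n)
  })
  d <- 1 - e
  if (sum(d) <= 0) stop("entropy degenerate: all indicators constant",
                        call. = FALSE)
  out <- data.frame(indicator = colnames(R), entropy = unname(e),
                    weight = unname(d / sum(d)))
  class(out) <- c("entropy_weights", "data.frame")
  out
}

#' TOPSIS closeness to the ideal solution
#'
#' Weights the normalized matrix (`v_ij = w_j r_ij`), takes the positive
#' ideal as the column-wise maximum and the negative ideal as the
#' column-wise minimum, computes Euclidean distances `D+` and `D-` to
#' each, and scores every entity by relative closeness
#' `C = D- / (D+ + D-)`, in \[0, 1\] with 1 at the positive (most toxic)
#' ideal.
#'
#' @param R Normalized matrix from [orient_normalize()].
#' @param w An [entropy_weights()] table (or numeric weight vector over
#'   the columns of `R`).
#' @return Data frame of class `mcda_result` with columns `name`,
#'   `d_plus`, `d_minus`, `closeness`, sorted by closeness descending;
#'   the weight vector is attached as attribute `weights`.
#' @export
topsis_scores <- function(R, w) {
  R <- as.matrix(R)
  if (nrow(R) < 2) stop("need >= 2 entities", call. = FALSE)
  if (is.data.frame(w)) {
    wv <- stats::setNames(w$weight, w$indicator)[colnames(R)]
  } else {
    wv <- if (is.null(names(w))) stats::setNames(w, colnames(R)) else w[colnames(R)]
  }
  if (anyNA(wv) || any(wv < 0)) stop("invalid weights", call. = FALSE)
  V <- sweep(R, 2, wv, "*")
  ideal_pos <- apply(V, 2, max)
  ideal_neg <- apply(V, 2, min)
  d_plus <- sqrt(rowSums(sweep(V, 2, ideal_pos, "-")^2))
  d_minus <- sqrt(rowSums(sweep(V, 2, ideal_neg, "-")^2))
  if (all(d_plus + d_minus == 0)) {
    stop("no discrimination: all entities identical", call. = FALSE)
  }
  C <- d_minus / (d_plus + d_minus)
  out <- data.frame(name = rownames(R), d_plus = d_plus, d_minus = d_minus,
                    closeness = C, row.names = NULL)
  out <- out[order(-out$closeness, out$name), ]
  rownames(out) <- NULL
  attr(out, "weights") <- wv
  class(out) <- c("mcda_result", "data.frame")
  out
}

#' Adjusted comprehensive toxicity of transformation products
#'
#' A product's adjusted score is the mean of its 24 oriented-normalized
#' indicators multiplied by its TOPSIS closeness, sharpening the ranking
#' of products that are both broadly and relatively toxic.
#'
#' @param T_products A [toxicity_matrix()] of products.
#' @param res An `mcda_result` computed on the oriented-normalized
#'   product matrix.
#' @return Named numeric vector of adjusted scores (one per product).
#' @export
adjusted_product_scores <- function(T_products, res) {
  stopifnot(inherits(T_products, "toxicity_matrix"))
  R <- orient_normalize(T_products)
  if (!setequal(res$name, rownames(R))) {
    stop("entity names in result do not match the product matrix",
         call. = FALSE)
  }
  means <- rowMeans(R)[res$name]
  stats::setNames(unname(means) * res$closeness, res$name)
}

#' Aggregate parent and transformation-product toxicity
#'
#' Per parent, the combined indicator vector is the weighted mixture of
#' the parent's own vector and the mean vector over its products
#' (default half/half); a parent with zero products keeps its own vector.
#'
#' @param parents A [toxicity_matrix()] of parent compounds.
#' @param products A [toxicity_matrix()] of products (same indicator set).
#' @param map A [transformation_map()]; every parent in it must be a row
#'   of `parents`, every product a row of `products`.
#' @param parent_weight Weight of the parent vector (default 0.5).
#' @return A [toxicity_matrix()] with one row per parent of `parents`.
#' @export
aggregate_parent_products <- function(parents, products, map,
                                      parent_weight = 0.5) {
  stopifnot(inherits(parents, "toxicity_matrix"),
            inherits(products, "toxicity_matrix"))
  if (parent_weight < 0 || parent_weight > 1) {
    stop("parent_weight must lie in [0, 1]")
  }
  if (!setequal(colnames(parents$values), colnames(products$values))) {
    stop("parents and products must share the indicator set", call. = FALSE)
  }
  missing_parents <- setdiff(names(map), rownames(parents$values))
  if (length(missing_parents)) {
    stop("parent(s) in map missing from matrix: ",
         paste(missing_parents, collapse = ", "), call. = FALSE)
  }
  missing_prods <- setdiff(unlist(map), rownames(products$values))
  if (length(missing_prods)) {
    stop("product(s) referenced but missing: ",
         paste(missing_prods, collapse = ", "), call. = FALSE)
  }
  pv <- products$values[, colnames(parents$values), drop = FALSE]
  out <- parents$values
  for (p in rownames(out)) {
    prods <- if (p %in% names(map)) map[[p]] else character()
    if (length(prods) == 0) next
    prod_mean <- colMeans(pv[prods, , drop = FALSE])
    out[p, ] <- parent_weight * parents$values[p, ] +
      (1 - parent_weight) * prod_mean
  }
  toxicity_matrix(out, orientation = parents$orientation)
}

#' Composite toxicity scoring pipeline
#'
#' End-to-end comprehensive toxicity: aggregate each parent with the mean
#' of its transformation products ([aggregate_parent_products()]),
#' orientation-normalize, weight the indicators by entropy, and score by
#' TOPSIS closeness.
#'
#' @inheritParams aggregate_parent_products
#' @return List with `combined` (aggregated [toxicity_matrix()]),
#'   `weights` ([entropy_weights()] table) and `mcda` (`mcda_result`).
#' @export
score_composite_toxicity <- function(parents, products = NULL, map = NULL,
                                     parent_weight = 0.5) {
  combined <- if (is.null(products) || is.null(map)) parents else
    aggregate_parent_products(parents, products, map, parent_weight)
  R <- orient_normalize(combined)
  w <- entropy_weights(R)
  list(combined = combined, weights = w, mcda = topsis_scores(R, w))
}
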