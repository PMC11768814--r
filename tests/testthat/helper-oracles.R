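# Independent brute-force references for the entropy-weight and TOPSIS
# formulas, written as direct loops over the definitions so they share no
# code with the package implementations.

oracle_entropy <- function(R) {
  n <- nrow(R); k <- ncol(R)
  e <- numeric(k)
  for (j in seq_len(k)) {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + R[i, j]
    if (tot == 0) { e[j] <- 1; next }
    s <- 0
    for (i in seq_len(n)) {
      p <- R[i, j] / tot
      if (p > 0) s <- s + p * log(p)
    }
    e[j] <- -s / log(n)
  }
  d <- 1 - e
  list(entropy = e, weight = d / sum(d))
}

oracle_topsis <- function(R, w) {
  n <- nrow(R); k <- ncol(R)
  V <- matrix(0, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) V[i, j] <- R[i, j] * w[j]
  best <- apply(V, 2, max); worst <- apply(V, 2, min)
  dp <- dm <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sm <- 0
    for (j in seq_len(k)) {
      sp <- sp + (V[i, j] - best[j])^2
      sm <- sm + (V[i, j] - worst[j])^2
    }
    dp[i] <- sqrt(sp); dm[i] <- sqrt(sm)
  }
  list(d_plus = dp, d_minus = dm, closeness = dm / (dp + dm))
}

# fixed corpus of small nonnegative matrices (dims up to 6 x 4)
small_matrix_corpus <- function() {
  corpus <- list()
  set.seed(42)
  for (n in 2:6) for (k in 2:4) {
    R <- matrix(runif(n * k), n, k,
                dimnames = list(sprintf("e%d", seq_len(n)),
                                sprintf("i%d", seq_len(k))))
    corpus[[length(corpus) + 1L]] <- R
  }
  # include a matrix with exact zeros and one with a near-constant column
  R0 <- matrix(c(1, 0.5, 0, 0.5, 1, 0.5), 3, 2,
               dimnames = list(c("a", "b", "c"), c("i1", "i2")))
  corpus[[length(corpus) + 1L]] <- R0
  corpus
}

# toxicity matrix over the canonical 24-indicator panel from raw draws
random_toxicity <- function(n, seed = 1) {
  set.seed(seed)
  nm <- opswatch::toxicity_indicator_names()
  vals <- matrix(runif(n * 24), nrow = n,
                 dimnames = list(sprintf("ent_%02d", seq_len(n)), nm))
  vals[, c("BCF", "IGC50", "LC50DM", "LC50FM")] <-
    exp(matrix(rnorm(n * 4), n))
  opswatch::toxicity_matrix(vals)
}
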