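# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic test-bed generator
#'
#' Defaults mirror the study conditions of the analysis the package
#' reproduces: 79 molecules split 17/8/54 across the banned / restricted /
#' unrestricted classes, a descriptor table with correlated redundant
#' blocks and sporadically missing columns, a 24-indicator toxicity panel
#' (20 probability endpoints, 4 continuous eco-endpoints), and 0--8
#' environmental transformation products per parent whose toxicity is a
#' convex mixture of the parent profile and a fresh draw.
#'
#' @param n_molecules Number of parent molecules.
#' @param class_proportions Length-3 y1 class proportions
#'   (banned, restricted, unrestricted); must sum to 1.
#' @param n_descriptors Total descriptor columns.
#' @param n_informative Descriptors whose class-conditional means differ;
#'   each heads one redundant block.
#' @param effect_size Standardized separation between adjacent class means
#'   in informative descriptors (unit within-class SD).
#' @param block_size Columns per redundant block (the informative column
#'   plus `block_size - 1` correlated copies).
#' @param block_rho Target within-block Pearson correlation, in \[0, 1).
#' @param missing_rate Fraction of descriptor columns receiving injected
#'   missing cells.
#' @param indicator_concentrations 24 x 2 numeric matrix, rows named by
#'   [toxicity_indicator_names()]. For the 20 probability indicators the
#'   two columns are Beta shape parameters; for BCF / IGC50 / LC50DM /
#'   LC50FM they are log-normal meanlog and sdlog.
#' @param n_products_mean Poisson mean of the per-parent product count,
#'   truncated to \[0, 8\].
#' @param parent_mix Weight `lambda` of the parent profile in product
#'   toxicity, in \[0, 1\].
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 79,
                             class_proportions = c(17, 8, 54) / 79,
                             n_descriptors = 200,
                             n_informative = 20,
                             effect_size = 1.5,
                             block_size = 5,
                             block_rho = 0.97,
                             missing_rate = 0.05,
                             indicator_concentrations = default_concentrations(),
                             n_products_mean = 4,
                             parent_mix = 0.6,
                             seed = 1) {
  stopifnot(n_molecules >= 2, length(class_proportions) == 3,
            n_descriptors >= 1, n_informative >= 0, block_size >= 1)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)")
  if (parent_mix < 0 || parent_mix > 1) stop("parent_mix must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  ic <- as.matrix(indicator_concentrations)
  if (!identical(dim(ic), c(24L, 2L)) ||
      !setequal(rownames(ic), toxicity_indicator_names())) {
    stop("indicator_concentrations must be 24 x 2 with canonical indicator rownames")
  }
  if (any(ic[probability_indicator_names(), ] <= 0)) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  structure(list(n_molecules = n_molecules,
                 class_proportions = class_proportions,
                 n_descriptors = n_descriptors,
                 n_informative = n_informative,
                 effect_size = effect_size,
                 block_size = block_size,
                 block_rho = block_rho,
                 missing_rate = missing_rate,
                 indicator_concentrations = ic[toxicity_indicator_names(), ],
                 n_products_mean = n_products_mean,
                 parent_mix = parent_mix,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default indicator distribution parameters
#'
#' A fixed heterogeneous panel emulating a real ADMET-style output: a few
#' near-certain endpoints (genotoxicity, hepatotoxicity, respiratory
#' toxicity with Beta means > 0.9), one strongly dispersed endpoint
#' (ototoxicity, a U-shaped Beta, mirroring the large between-molecule
#' variation that gives it the top entropy weight in real panels),
#' moderately informative mid-range endpoints, and log-normal continuous
#' eco-endpoints.
#'
#' @return 24 x 2 numeric matrix with indicator rownames.
#' @export
default_concentrations <- function() {
  nm <- toxicity_indicator_names()
  m <- matrix(0, nrow = 24, ncol = 2, dimnames = list(nm, c("par1", "par2")))
  m[probability_indicator_names(), ] <- matrix(rep(c(2, 2), 20),
                                               ncol = 2, byrow = TRUE)
  m["genotoxicity", ] <- c(14, 0.5)
  m["human_hepatotoxicity", ] <- c(10, 0.8)
  m["respiratory_toxicity", ] <- c(8, 1)
  m["eye_irritation", ] <- c(6, 1.5)
  m["skin_sensitization", ] <- c(5, 2)
  m["ototoxicity", ] <- c(0.25, 0.4)
  m["nematotoxicity", ] <- c(0.8, 2.5)
  m["carcinogenicity", ] <- c(3, 1.5)
  m["eye_corrosion", ] <- c(1, 4)
  m["hERG_blockers_10um", ] <- c(1.2, 3)
  m["BCF", ] <- c(1, 0.5)      # meanlog, sdlog
  m["IGC50", ] <- c(2, 0.5)
  m["LC50DM", ] <- c(2, 0.5)
  m["LC50FM", ] <- c(2, 0.5)
  m
}

# Deterministic class sizes by largest remainder, summing to n.
class_counts <- function(n, proportions) {
  raw <- n * proportions
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[add] <- k[add] + 1
  }
  as.integer(k)
}

#' Generate a descriptor matrix with planted class signal
#'
#' Informative descriptors are class-conditional Gaussians (unit
#' within-class SD, adjacent class means separated by `effect_size`); each
#' informative column heads a redundant block of `block_size` columns whose
#' extra members are noisy copies with within-block Pearson correlation
#' about `block_rho`. Remaining columns are pure standard-normal noise.
#' A fraction `missing_rate` of columns receives injected missing cells.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `descriptors` (matrix, carrying attributes
#'   `informative` and `blocks` naming the planted structure) and `labels`
#'   (y1 factor per molecule).
#' @export
generate_descriptors <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_molecules
  p <- cfg$n_descriptors
  if (cfg$n_informative * cfg$block_size > p) {
    stop("n_informative * block_size exceeds n_descriptors", call. = FALSE)
  }
  with_seed(cfg$seed, {
    counts <- class_counts(n, cfg$class_proportions)
    y <- factor(rep(regulatory_levels("y1"), counts),
                levels = regulatory_levels("y1"))
    cls <- as.integer(y)
    X <- matrix(stats::rnorm(n * p), nrow = n)
    rownames(X) <- sprintf("mol_%03d", seq_len(n))
    colnames(X) <- sprintf("desc_%04d", seq_len(p))
    blocks <- list()
    informative <- character()
    for (b in seq_len(cfg$n_informative)) {
      j0 <- (b - 1L) * cfg$block_size + 1L
      mu <- sample(0:2) * cfg$effect_size  # random class-to-mean assignment
      x <- stats::rnorm(n) + mu[cls]
      X[, j0] <- x
      xs <- as.vector(scale(x))
      cols <- j0
      for (k in seq_len(cfg$block_size - 1L)) {
        X[, j0 + k] <- cfg$block_rho * xs +
          sqrt(1 - cfg$block_rho^2) * stats::rnorm(n)
        cols <- c(cols, j0 + k)
      }
      informative <- c(informative, colnames(X)[j0])
      blocks[[b]] <- colnames(X)[cols]
    }
    n_miss <- round(cfg$missing_rate * p)
    if (n_miss > 0) {
      miss_cols <- sample(p, n_miss)
      for (j in miss_cols) {
        cells <- sample(n, max(1L, stats::rbinom(1, n, 0.1)))
        X[cells, j] <- NA_real_
      }
    }
    attr(X, "informative") <- informative
    attr(X, "blocks") <- blocks
    list(descriptors = X, labels = y)
  })
}

#' Generate a toxicity-indicator matrix
#'
#' Probability indicators are Beta draws with per-indicator shapes; BCF
#' and the three lethal/inhibitory concentrations are log-normal, the
#' latter three carrying cost orientation (lower = more toxic). Entities
#' named in `planted` are drawn from the toxic tail of every indicator:
#' the top `1 - plant_quantile` quantile range for benefit-oriented
#' columns, the bottom for cost-oriented ones.
#'
#' @param cfg A [synthetic_config()].
#' @param names Entity names (one row each).
#' @param planted Subset of `names` to receive tail-shifted draws.
#' @param plant_quantile Quantile defining the toxic tail (default 0.9 =
#'   top decile).
#' @return A [toxicity_matrix()].
#' @export
generate_toxicity <- function(cfg, names, planted = character(),
                              plant_quantile = 0.9) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_axis_names(names, "entity")
  bad <- setdiff(planted, names)
  if (length(bad)) stop("planted entities not in names: ",
                        paste(bad, collapse = ", "))
  with_seed(cfg$seed + 1L, {
    vals <- draw_toxicity_rows(cfg, length(names),
                               planted = names %in% planted,
                               plant_quantile = plant_quantile)
    rownames(vals) <- names
    toxicity_matrix(vals)
  })
}

# Draw `n` toxicity rows; `planted` is a logical vector of length n.
draw_toxicity_rows <- function(cfg, n, planted = rep(FALSE, n),
                               plant_quantile = 0.9) {
  ic <- cfg$indicator_concentrations
  nm <- toxicity_indicator_names()
  orientation <- default_orientation()
  vals <- matrix(0, nrow = n, ncol = length(nm), dimnames = list(NULL, nm))
  for (j in nm) {
    u <- stats::runif(n)
    # toxic tail: high quantiles for benefit columns, low for cost columns
    if (orientation[[j]] == "benefit") {
      u[planted] <- plant_quantile + u[planted] * (1 - plant_quantile)
    } else {
      u[planted] <- u[planted] * (1 - plant_quantile)
    }
    if (j %in% probability_indicator_names()) {
      vals[, j] <- stats::qbeta(u, ic[j, 1], ic[j, 2])
    } else {
      vals[, j] <- stats::qlnorm(u, meanlog = ic[j, 1], sdlog = ic[j, 2])
    }
  }
  vals
}

#' Generate environmental transformation products
#'
#' Per parent, a truncated-Poisson number of products (mean
#' `n_products_mean`, support \[0, 8\]); each product's indicator vector is
#' the convex mixture `lambda * parent + (1 - lambda) * fresh draw` with
#' `lambda = parent_mix`, so products inherit their parent's toxicity
#' profile to a controllable degree.
#'
#' @param cfg A [synthetic_config()].
#' @param parents A [toxicity_matrix()] of parent compounds.
#' @return List with `map` (a [transformation_map()]) and `products`
#'   (a [toxicity_matrix()], one row per product).
#' @export
generate_products <- function(cfg, parents) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(parents, "toxicity_matrix"))
  with_seed(cfg$seed + 2L, {
    pn <- rownames(parents$values)
    lambda <- cfg$parent_mix
    # inverse-CDF truncated Poisson on [0, 8]
    u <- stats::runif(length(pn)) * stats::ppois(8, cfg$n_products_mean)
    k <- stats::qpois(u, cfg$n_products_mean)
    map <- stats::setNames(vector("list", length(pn)), pn)
    rows <- list()
    for (i in seq_along(pn)) {
      if (k[i] == 0) { map[[i]] <- character(); next }
      fresh <- draw_toxicity_rows(cfg, k[i])
      mixed <- lambda * matrix(parents$values[i, ], nrow = k[i],
                               ncol = ncol(fresh), byrow = TRUE) +
        (1 - lambda) * fresh
    colnames(mixed) <- colnames(fresh)
      prods <- sprintf("%s_tp%d", pn[i], seq_len(k[i]))
      rownames(mixed) <- prods
      map[[i]] <- prods
      rows[[length(rows) + 1L]] <- mixed
    }
    vals <- if (length(rows)) do.call(rbind, rows) else
      matrix(0, nrow = 0, ncol = ncol(parents$values),
             dimnames = list(character(), colnames(parents$values)))
    list(map = transformation_map(map), products = toxicity_matrix(vals))
  })
}
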