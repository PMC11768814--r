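test_that("the 7:3 split follows the floor convention and stratifies", {
  y <- rep(regulatory_levels("y1"), c(17, 8, 54))
  sp <- split_dataset(y, 0.7, seed = 1)
  expect_length(sp$train, 55)
  expect_length(sp$test, 24)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_equal(unname(table(y[sp$test])), c(5L, 3L, 16L), ignore_attr = TRUE)
  expect_identical(sp, split_dataset(y, 0.7, seed = 1))
  expect_false(identical(sp$train, split_dataset(y, 0.7, seed = 2)$train))
  expect_error(split_dataset(y, 1.0), "ratio")
  expect_error(split_dataset(factor(y, levels = c(regulatory_levels("y1"),
                                                  "ghost")), 0.7),
               "0 members")
})

test_that("every algorithm family fits, predicts valid labels, and is seeded", {
  cfg <- synthetic_config(n_molecules = 60, n_descriptors = 20,
                          n_informative = 4, block_size = 2,
                          effect_size = 2.5, missing_rate = 0, seed = 21)
  g <- generate_descriptors(cfg)
  X <- g$descriptors; y <- g$labels
  for (algo in algorithm_roster()) {
    hp <- if (algo == "ann") list(size = 8, maxit = 100) else list()
    m <- train_classifier(algo, X, y, hyperparameters = hp, seed = 5)
    p <- predict(m, X)
    expect_s3_class(p, "factor")
    expect_identical(levels(p), regulatory_levels("y1"))
    expect_length(p, nrow(X))
    m2 <- train_classifier(algo, X, y, hyperparameters = hp, seed = 5)
    expect_identical(predict(m2, X), p)
  }
})

test_that("strong planted signal is learnable and training accuracy is high", {
  accs <- vapply(1:10, function(s) {
    g <- generate_descriptors(synthetic_config(n_molecules = 60,
                                               n_descriptors = 30,
                                               n_informative = 5,
                                               block_size = 2,
                                               effect_size = 3,
                                               missing_rate = 0, seed = s))
    m <- train_classifier("rf", g$descriptors, g$labels, seed = s)
    mean(predict(m, g$descriptors) == g$labels)
  }, numeric(1))
  expect_gt(median(accs), 0.95)
})

test_that("a linearly separable toy is solved exactly by logistic regression", {
  X <- matrix(c(seq(-2, -1, length.out = 10), seq(1, 2, length.out = 10)),
              ncol = 1, dimnames = list(paste0("m", 1:20), "x"))
  y <- rep(c("lo", "hi"), each = 10)
  m <- train_classifier("lr", X, y, seed = 1)
  expect_equal(mean(predict(m, X) == y), 1.0)
})

test_that("prediction rejects feature mismatches by name", {
  g <- generate_descriptors(synthetic_config(n_molecules = 30,
                                             n_descriptors = 10,
                                             n_informative = 2,
                                             block_size = 2,
                                             missing_rate = 0, seed = 2))
  m <- train_classifier("rf", g$descriptors, g$labels, seed = 1)
  X2 <- g$descriptors[, -3]
  expect_error(predict(m, X2), "desc_0003")
  Xbad <- g$descriptors; Xbad[1, 1] <- Inf
  expect_error(train_classifier("rf", Xbad, g$labels), "non-finite")
  expect_error(train_classifier("pls", g$descriptors, g$labels))
})

test_that("the metric suite matches a hand-computed 3-class table", {
  # truth supports (5, 3, 2); one restricted molecule predicted unrestricted
  truth <- rep(c("banned", "restricted", "unrestricted"), c(5, 3, 2))
  pred <- truth; pred[7] <- "unrestricted"
  ev <- evaluate(pred, truth, regulatory_levels("y1"))
  expect_equal(sum(ev$confusion), 10)
  expect_equal(ev$confusion["unrestricted", "restricted"], 1)
  expect_equal(ev$metrics$accuracy, 0.9)
  expect_equal(ev$metrics$recall, 0.9)
  expect_equal(ev$metrics$precision, (5 * 1 + 3 * 1 + 2 * (2 / 3)) / 10)
  expect_equal(ev$metrics$f1, (5 * 1 + 3 * 0.8 + 2 * 0.8) / 10)

  perfect <- evaluate(truth, truth, regulatory_levels("y1"))
  expect_equal(perfect$metrics$accuracy, 1)
  expect_equal(perfect$metrics$f1, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_error(evaluate(c("banned", "ghost"), c("banned", "banned"),
                        regulatory_levels("y1")), "ghost")
})

test_that("support-weighted recall equals accuracy on every complete evaluation", {
  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    classes <- letters[1:k]
    truth <- sample(classes, 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.6, truth, sample(classes, 40, replace = TRUE))
    ev <- evaluate(pred, truth, classes)
    expect_equal(ev$metrics$recall, ev$metrics$accuracy, tolerance = 1e-12)
  }
})

test_that("external validation reuses the metric suite on untouched data", {
  g <- generate_descriptors(synthetic_config(n_molecules = 40,
                                             n_descriptors = 15,
                                             n_informative = 3,
                                             block_size = 2,
                                             effect_size = 3,
                                             missing_rate = 0, seed = 12))
  m <- train_classifier("rf", g$descriptors, g$labels, seed = 1)
  insample <- evaluate(predict(m, g$descriptors), g$labels, m$classes)
  ext <- external_validate(m, g$descriptors, g$labels)
  expect_equal(ext$metrics$accuracy, insample$metrics$accuracy)
  expect_equal(ext$confusion, insample$confusion)
  expect_error(external_validate(m, g$descriptors[0, ], character()),
               "empty external set")
})

test_that("application tallying counts every molecule exactly once", {
  g <- generate_descriptors(synthetic_config(n_molecules = 40,
                                             n_descriptors = 15,
                                             n_informative = 3,
                                             block_size = 2,
                                             missing_rate = 0, seed = 13))
  m <- train_classifier("rf", g$descriptors, g$labels, seed = 1)
  out <- apply_and_tally(m, g$descriptors)
  expect_equal(sum(out$counts), nrow(g$descriptors))
  expect_identical(names(out$counts), regulatory_levels("y1"))
  empty <- apply_and_tally(m, g$descriptors[0, ])
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  same <- g$descriptors[rep(1, 7), ]
  rownames(same) <- paste0("r", 1:7)
  rep_out <- apply_and_tally(m, same)
  expect_equal(max(rep_out$counts), 7L)
})

test_that("zero-signal data keeps every algorithm at the chance floor", {
  # 3 binomial standard errors around the test-set majority share
  fams <- c("rf", "xgboost", "cnb", "knn", "lr", "svm")
  for (s in 1:3) {
    g <- generate_descriptors(synthetic_config(n_molecules = 60,
                                               n_descriptors = 20,
                                               n_informative = 4,
                                               block_size = 2,
                                               effect_size = 0,
                                               missing_rate = 0, seed = s))
    sp <- split_dataset(g$labels, 0.7, seed = s)
    maj <- max(table(g$labels[sp$test])) / length(sp$test)
    se <- sqrt(maj * (1 - maj) / length(sp$test))
    for (algo in fams) {
      m <- train_classifier(algo, g$descriptors[sp$train, ],
                            g$labels[sp$train], seed = s)
      acc <- mean(predict(m, g$descriptors[sp$test, ]) == g$labels[sp$test])
      expect_lte(acc, maj + 3 * se)
    }
  }
})

test_that("cross-validated tuning returns a grid member and a working model", {
  g <- generate_descriptors(synthetic_config(n_molecules = 60,
                                             n_descriptors = 12,
                                             n_informative = 3,
                                             block_size = 2,
                                             effect_size = 2,
                                             missing_rate = 0, seed = 31))
  m <- train_classifier("knn", g$descriptors, g$labels, seed = 2, tune = TRUE)
  expect_true(m$hyperparameters$k %in% c(3, 5, 7))
  expect_length(predict(m, g$descriptors), nrow(g$descriptors))
})
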