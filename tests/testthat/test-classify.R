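# Classifiers, grid search, cross-validation, evaluation report.

make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
      cbind(rnorm(n_per, centers[k, 1], sd),
            rnorm(n_per, centers[k, 2], sd))))
    colnames(X) <- c("u", "v")
    list(X = X, y = rep(LETTERS[seq_len(nrow(centers))], each = n_per))
  })
}

hex_centers <- 3 * cbind(cos(1:6), sin(1:6))

test_that("default grids contain the reference best points", {
  expect_true(any(vapply(rf_default_grid(), identical, logical(1),
                         best_reference_params("rf"))))
  expect_true(any(vapply(mlp_default_grid(), function(g)
    identical(g, best_reference_params("mlp")), logical(1))))
})

test_that("probabilities are valid and name-keyed", {
  b <- make_blobs(30, hex_centers)
  for (fam in c("rf", "mlp")) {
    params <- if (fam == "rf")
      list(criterion = "entropy", max_depth = 10L, mtry = 2L,
           min_leaf = 1L, min_split = 5L, n_trees = 30L)
    else
      list(activation = "tanh", hidden = c(16L, 8L), max_iter = 60L,
           batch_size = 32L, learning_rate = 1e-2)
    m <- train_model(b$X, b$y, fam, params, seed = 2)
    P <- predict_proba(m, b$X)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
    expect_true(all(P >= 0))
    # permuting named columns leaves predictions unchanged
    P2 <- predict_proba(m, b$X[, c("v", "u")])
    expect_equal(P2, P)
    expect_error(predict_proba(m, b$X[, "u", drop = FALSE]), "missing")
    # deterministic refit
    m2 <- train_model(b$X, b$y, fam, params, seed = 2)
    expect_equal(predict_proba(m2, b$X), P)
  }
})

test_that("well separated blobs are learned to training accuracy 1", {
  b <- make_blobs(25, hex_centers, sd = 0.15, seed = 3)
  for (fam in c("rf", "mlp")) {
    params <- if (fam == "rf")
      list(criterion = "gini", max_depth = 12L, mtry = 2L, min_leaf = 1L,
           min_split = 2L, n_trees = 50L)
    else
      list(activation = "tanh", hidden = c(32L, 16L), max_iter = 150L,
           batch_size = 50L, learning_rate = 1e-2)
    m <- train_model(b$X, b$y, fam, params, seed = 4)
    pred <- colnames(predict_proba(m, b$X))[
      max.col(predict_proba(m, b$X), ties.method = "first")]
    expect_equal(mean(pred == b$y), 1.0)
  }
})

test_that("stratified folds partition each class evenly", {
  y <- rep(letters[1:4], times = c(40, 40, 20, 20))
  f <- stratified_folds(y, k = 10, seed = 5)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(length(f), 120)
  tab <- table(y, f)
  expect_true(all(tab[1:2, ] == 4))
  expect_true(all(tab[3:4, ] == 2))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 50)), k = 10),
               "degenerate")
})

test_that("grid search picks the better point; single point passthrough", {
  b <- make_blobs(40, hex_centers, sd = 1.0, seed = 6)  # noisy classes
  single <- list(best_reference_params("rf"))
  gs1 <- grid_search(b$X, b$y, "rf", single, folds = 4, seed = 7)
  expect_identical(gs1$best, single[[1]])
  weak <- list(criterion = "entropy", max_depth = 1L, mtry = 1L,
               min_leaf = 1L, min_split = 2L, n_trees = 1L)
  strong <- list(criterion = "entropy", max_depth = 10L, mtry = 2L,
                 min_leaf = 1L, min_split = 5L, n_trees = 100L)
  gs <- grid_search(b$X, b$y, "rf", list(weak, strong), folds = 5,
                    seed = 8)
  expect_identical(gs$best, strong)
  expect_gt(gs$cv_accuracy[2], gs$cv_accuracy[1])
})

test_that("evaluation report: perfect, chance-level, and CI behavior", {
  b <- make_blobs(40, hex_centers, sd = 0.15, seed = 9)
  params <- list(criterion = "gini", max_depth = 12L, mtry = 2L,
                 min_leaf = 1L, min_split = 2L, n_trees = 50L)
  m <- train_model(b$X, b$y, "rf", params, seed = 10)
  rep1 <- evaluate_model(m, b$X, b$y, n_boot = 200, seed = 11)
  expect_equal(rep1$metrics$value, rep(1, 5))
  expect_true(all(diag(rep1$confusion) == 40))
  expect_equal(unname(rowSums(rep1$confusion)), rep(40L, 6))
  expect_true(all(rep1$metrics$lower <= rep1$metrics$value))
  expect_true(all(rep1$metrics$upper >= rep1$metrics$value))

  # chance level: uniform random probabilities on balanced 6 classes
  n <- 1440
  yb <- rep(LETTERS[1:6], each = n / 6)
  withr::with_seed(12, {
    P <- matrix(runif(n * 6), n, 6)
    P <- P / rowSums(P)
    colnames(P) <- LETTERS[1:6]
  })
  pred <- factor(speckleid:::model_classes_pred(P), levels = LETTERS[1:6])
  cm <- table(factor(yb, LETTERS[1:6]), pred)
  mm <- speckleid:::macro_metrics(cm)
  expect_lt(abs(mm[["accuracy"]] - 1 / 6), 0.05)
  expect_lt(abs(speckleid:::macro_auc(P, yb) - 0.5), 0.05)
})

test_that("bootstrap CIs contract as the test set grows", {
  width_at <- function(n_per) {
    b <- make_blobs(n_per, hex_centers, sd = 1.2, seed = 13)
    m <- train_model(b$X, b$y, "rf",
                     list(criterion = "gini", max_depth = 8L, mtry = 2L,
                          min_leaf = 1L, min_split = 2L, n_trees = 40L),
                     seed = 14)
    te <- make_blobs(n_per, hex_centers, sd = 1.2, seed = 15)
    r <- evaluate_model(m, te$X, te$y, n_boot = 300, seed = 16)
    acc <- r$metrics[r$metrics$metric == "accuracy", ]
    acc$upper - acc$lower
  }
  expect_lt(width_at(240), width_at(24))
})

test_that("degenerate inputs error clearly", {
  b <- make_blobs(10, hex_centers[1:2, ])
  expect_error(train_model(b$X, rep("a", 20), "rf"), "2 classes")
  m <- train_model(b$X, b$y, "rf",
                   list(criterion = "gini", max_depth = 3L, mtry = 1L,
                        min_leaf = 1L, min_split = 2L, n_trees = 5L))
  expect_error(evaluate_model(m, b$X, rep("Z", 20)), "classes")
})
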