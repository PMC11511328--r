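# Classification models: a CART-style Random Forest and a Multi-Layer
# Perceptron, both implemented natively (no external learners), with a
# name-keyed predict_proba contract, stratified k-fold grid search, and
# a bootstrap-CI evaluation report.

node_impurity <- function(counts, criterion) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  if (criterion == "entropy") -sum(p * log(p)) else 1 - sum(p^2)
}

# Best split over a random subset of features. Returns NULL when no
# admissible split improves impurity.
best_split <- function(X, y, n_classes, mtry, min_leaf, criterion) {
  n <- nrow(X); p <- ncol(X)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  tot <- tabulate(y, n_classes)
  h0 <- node_impurity(tot, criterion)
  best <- NULL; best_score <- h0 - 1e-12
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  for (f in feats) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]
    cum <- apply(Y[ord, , drop = FALSE], 2, cumsum)
    if (n_classes == 1L) cum <- matrix(cum, ncol = 1L)
    s <- seq_len(n - 1L)
    ok <- xs[s] < xs[s + 1L] & s >= min_leaf & (n - s) >= min_leaf
    if (!any(ok)) next
    s <- s[ok]
    nl <- s; nr <- n - s
    pl <- cum[s, , drop = FALSE] / nl
    pr <- (rep(tot, each = length(s)) - cum[s, , drop = FALSE]) / nr
    imp <- function(pm) {
      t <- pm * log(pm); t[!is.finite(t)] <- 0
      -rowSums(t)
    }
    if (criterion == "entropy") {
      hl <- imp(pl); hr <- imp(pr)
    } else {
      hl <- 1 - rowSums(pl^2); hr <- 1 - rowSums(pr^2)
    }
    score <- (nl * hl + nr * hr) / n
    b <- which.min(score)
    if (score[b] < best_score) {
      best_score <- score[b]
      best <- list(feature = f, threshold = (xs[s[b]] + xs[s[b] + 1L]) / 2)
    }
  }
  best
}

grow_tree <- function(X, y, n_classes, depth, max_depth, mtry, min_leaf,
                      min_split, criterion) {
  n <- length(y)
  counts <- tabulate(y, n_classes)
  if (depth >= max_depth || n < min_split || sum(counts > 0) == 1L)
    return(list(leaf = TRUE, probs = counts / n))
  sp <- best_split(X, y, n_classes, mtry, min_leaf, criterion)
  if (is.null(sp)) return(list(leaf = TRUE, probs = counts / n))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], n_classes,
                        depth + 1L, max_depth, mtry, min_leaf, min_split,
                        criterion),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], n_classes,
                         depth + 1L, max_depth, mtry, min_leaf, min_split,
                         criterion))
}

predict_tree <- function(tree, X, n_classes) {
  n <- nrow(X)
  out <- matrix(0, n, n_classes)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out[idx, ] <<- matrix(node$probs, length(idx), n_classes, byrow = TRUE)
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(tree, seq_len(n))
  out
}

fit_rf <- function(X, y, n_classes, params) {
  n <- nrow(X)
  trees <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X[boot, , drop = FALSE], y[boot], n_classes,
                            0L, params$max_depth, params$mtry,
                            params$min_leaf, params$min_split,
                            params$criterion)
  }
  trees
}

predict_rf <- function(trees, X, n_classes) {
  acc <- matrix(0, nrow(X), n_classes)
  for (tr in trees) acc <- acc + predict_tree(tr, X, n_classes)
  acc / length(trees)
}

mlp_activation <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) (a > 0) * 1),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(a) a * (1 - a)),
         stop("unknown activation: ", name))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Fully connected net with categorical cross-entropy loss, trained by
# Adam on shuffled minibatches for a fixed epoch budget (no early
# stopping). Inputs are z-scored with training statistics stored in the
# fit, since the texture features span several orders of magnitude.
fit_mlp <- function(X, y, n_classes, params) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sizes <- c(p, params$hidden, n_classes)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  act <- mlp_activation(params$activation)
  Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), y)] <- 1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  l2 <- if (is.null(params$l2)) 1e-4 else params$l2
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  step <- 0L
  bs <- min(params$batch_size, n)
  for (epoch in seq_len(params$max_iter)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      m <- length(idx)
      A <- vector("list", L + 1L)
      A[[1L]] <- Xs[idx, , drop = FALSE]
      for (l in seq_len(L - 1L))
        A[[l + 1L]] <- act$f(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
      A[[L + 1L]] <- softmax_rows(sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+"))
      delta <- (A[[L + 1L]] - Y[idx, , drop = FALSE]) / m
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * act$df(A[[l]])
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - params$learning_rate *
          (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - params$learning_rate *
          (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
    }
  }
  list(W = W, b = b, center = ctr, scale = scl,
       activation = params$activation)
}

predict_mlp <- function(fit, X) {
  A <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  act <- mlp_activation(fit$activation)
  L <- length(fit$W)
  for (l in seq_len(L - 1L))
    A <- act$f(sweep(A %*% fit$W[[l]], 2, fit$b[[l]], "+"))
  softmax_rows(sweep(A %*% fit$W[[L]], 2, fit$b[[L]], "+"))
}

#' Default hyperparameter grids
#'
#' Each grid brackets the reference best configuration (RF: entropy
#' criterion, depth 10, 4 features per split, min leaf 1, min split 5,
#' 250 trees; MLP: tanh, hidden (100, 25), 200 epochs, batch 200,
#' learning rate 0.001, Adam, cross-entropy) with one smaller and one
#' larger setting per parameter.
#'
#' @return A list of parameter lists, usable with [grid_search()].
#' @export
rf_default_grid <- function() {
  g <- expand.grid(criterion = c("gini", "entropy"),
                   max_depth = c(5L, 10L, 20L), mtry = c(2L, 4L, 8L),
                   min_leaf = c(1L, 2L), min_split = c(2L, 5L, 10L),
                   n_trees = c(100L, 250L, 500L),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    x <- as.list(g[i, ])
    attr(x, "out.attrs") <- NULL
    x
  })
}

#' @rdname rf_default_grid
#' @export
mlp_default_grid <- function() {
  out <- list()
  for (actv in c("tanh", "relu"))
    for (hid in list(50L, c(100L, 25L), c(200L, 50L)))
      for (it in c(100L, 200L, 300L))
        for (bsz in c(100L, 200L, 400L))
          for (lr in c(5e-4, 1e-3, 1e-2))
            out[[length(out) + 1L]] <-
              list(activation = actv, hidden = hid, max_iter = it,
                   batch_size = bsz, learning_rate = lr)
  out
}

#' Reference best hyperparameters
#' @param family `"rf"` or `"mlp"`.
#' @return A parameter list (one grid point).
#' @export
best_reference_params <- function(family = c("rf", "mlp")) {
  family <- match.arg(family)
  if (family == "rf")
    list(criterion = "entropy", max_depth = 10L, mtry = 4L, min_leaf = 1L,
         min_split = 5L, n_trees = 250L)
  else
    list(activation = "tanh", hidden = c(100L, 25L), max_iter = 200L,
         batch_size = 200L, learning_rate = 1e-3)
}

prepare_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  list(X = X, y = y, yi = as.integer(y), classes = levels(y))
}

#' Train a classifier
#'
#' @param X Feature table (matrix or data.frame) with column names.
#' @param y Class labels (coerced to factor).
#' @param family `"rf"` or `"mlp"`.
#' @param params Hyperparameter list (see [best_reference_params()]).
#' @param seed Integer seed; fits are deterministic given it.
#' @return An `sp_model`.
#' @export
train_model <- function(X, y, family = c("rf", "mlp"),
                        params = best_reference_params(family), seed = 1L) {
  family <- match.arg(family)
  d <- prepare_xy(X, y)
  if (length(d$classes) < 2L) stop("need at least 2 classes")
  fit <- withr::with_seed(seed, {
    if (family == "rf") fit_rf(d$X, d$yi, length(d$classes), params)
    else fit_mlp(d$X, d$yi, length(d$classes), params)
  })
  structure(list(family = family, fit = fit, classes = d$classes,
                 features = colnames(d$X), params = params, seed = seed),
            class = "sp_model")
}

#' Class-probability predictions
#'
#' Columns of `X` are matched to the model's training features by name,
#' so column order at predict time is irrelevant; missing features are
#' an error.
#'
#' @param model An `sp_model`. @param X New feature rows.
#' @return Matrix of class probabilities (rows sum to 1), columns named
#'   by class.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$features))
      stop("unnamed X with wrong number of columns")
    colnames(X) <- model$features
  }
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- X[, model$features, drop = FALSE]
  storage.mode(X) <- "double"
  P <- if (model$family == "rf")
    predict_rf(model$fit, X, length(model$classes))
  else predict_mlp(model$fit, X)
  colnames(P) <- model$classes
  P
}

#' Stratified k-fold assignment
#' @param y Factor of labels. @param k Number of folds. @param seed Seed.
#' @return Integer fold id per sample, each class spread across folds.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- factor(y)
  if (min(table(y)) < k)
    stop("degenerate folds: some class has fewer samples than folds")
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Grid search with stratified cross-validated accuracy
#'
#' Evaluates every grid point by k-fold cross-validation on the training
#' set and returns the point with the highest mean validation accuracy;
#' ties are broken by first-in-grid order.
#'
#' @inheritParams train_model
#' @param grid List of parameter lists.
#' @param folds Number of CV folds (default 10).
#' @return List: `best` (parameter list), `cv_accuracy` (per grid
#'   point), `best_index`.
#' @export
grid_search <- function(X, y, family = c("rf", "mlp"), grid,
                        folds = 10L, seed = 1L) {
  family <- match.arg(family)
  d <- prepare_xy(X, y)
  fold <- stratified_folds(d$y, folds, seed)
  acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(d$yi[tr])) < length(d$classes))
        stop("degenerate folds: a class is absent from a training fold")
      m <- train_model(d$X[tr, , drop = FALSE], d$y[tr], family,
                       params = grid[[gi]],
                       seed = derive_seed(seed, gi, f))
      P <- predict_proba(m, d$X[!tr, , drop = FALSE])
      pred <- model_classes_pred(P)
      correct <- correct + sum(pred == as.character(d$y[!tr]))
    }
    acc[gi] <- correct / length(d$y)
  }
  best <- which.max(acc)  # which.max returns the first maximum
  list(best = grid[[best]], cv_accuracy = acc, best_index = best)
}

model_classes_pred <- function(P) colnames(P)[max.col(P, ties.method = "first")]

macro_metrics <- function(cm) {
  k <- nrow(cm)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  c(accuracy = sum(tp) / n,
    sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec, na.rm = TRUE),
    precision = mean(prec, na.rm = TRUE))
}

auc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

macro_auc <- function(P, y) {
  mean(vapply(colnames(P), function(cl)
    auc_binary(P[, cl], y == cl), numeric(1)), na.rm = TRUE)
}

#' Evaluate a model on the test set
#'
#' Produces the confusion matrix (rows = true class, columns =
#' predicted), overall accuracy, macro-averaged one-vs-rest
#' sensitivity, specificity and precision, macro one-vs-rest AUC from
#' the class probabilities, and percentile bootstrap 95% confidence
#' intervals over test samples for all five metrics, plus per-class
#' one-vs-rest metrics.
#'
#' @param model An `sp_model`. @param X Test features. @param y Test labels.
#' @param n_boot Bootstrap resamples (default 1000). @param seed Seed.
#' @param conf Confidence level (default 0.95).
#' @return A `model_report` list: `confusion`, `metrics` (data.frame
#'   metric/value/lower/upper), `per_class`, `n_test`.
#' @export
evaluate_model <- function(model, X, y, n_boot = 1000L, seed = 1L,
                           conf = 0.95) {
  y <- factor(y, levels = model$classes)
  if (any(is.na(y))) stop("test labels outside the model's classes")
  if (length(y) == 0L) stop("empty test set")
  P <- predict_proba(model, X)
  pred <- factor(model_classes_pred(P), levels = model$classes)
  cm <- table(true = y, predicted = pred)
  point <- c(macro_metrics(cm), auc = macro_auc(P, as.character(y)))
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      cmb <- table(true = y[idx], predicted = pred[idx])
      c(macro_metrics(cmb), auc = macro_auc(P[idx, , drop = FALSE],
                                            as.character(y[idx])))
    }, numeric(5))
  })
  a <- (1 - conf) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  k <- nrow(cm)
  tp <- diag(cm); fn <- rowSums(cm) - tp; fp <- colSums(cm) - tp
  tn <- sum(cm) - tp - fn - fp
  per_class <- data.frame(
    class = rownames(cm),
    n = as.integer(rowSums(cm)),
    sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA),
    specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA),
    auc = vapply(rownames(cm), function(cl)
      auc_binary(P[, cl], as.character(y) == cl), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    confusion = unclass(cm),
    metrics = data.frame(metric = names(point), value = unname(point),
                         lower = unname(pmin(ci[1, ], point)),
                         upper = unname(pmax(ci[2, ], point)),
                         stringsAsFactors = FALSE),
    per_class = per_class, n_test = length(y), n_boot = n_boot,
    family = model$family, params = model$params),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report (%s, n_test=%d)\n", x$family, x$n_test))
  print(round(x$metrics[, c("value", "lower", "upper")], 3))
  invisible(x)
}
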