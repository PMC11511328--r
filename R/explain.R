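# Model-agnostic Shapley-value attribution with marginal background
# replacement: exact subset enumeration for small feature counts,
# Monte-Carlo permutation sampling otherwise.

#' Shapley-value attributions for tabular predictions
#'
#' Distributes each predicted class probability among the input features
#' using Shapley values with the marginal (interventional) value
#' function: the value of a coalition S is the mean prediction over the
#' background set with the features in S fixed to the explained sample.
#' With `exact = TRUE` (the default when the model has at most
#' `exact_limit` features) all 2^p coalitions are enumerated and the
#' efficiency, symmetry and dummy axioms hold to numerical precision;
#' otherwise a seeded Monte-Carlo permutation estimator is used.
#'
#' @param predict_fn Function taking a feature matrix (with column
#'   names) and returning a matrix of per-class outputs.
#' @param background Background feature matrix/data.frame (non-empty).
#' @param samples Feature rows to explain.
#' @param n_permutations Permutations per sample in sampling mode.
#' @param seed Integer seed.
#' @param exact Force exact enumeration (`TRUE`/`FALSE`); `NULL` picks
#'   exact when p <= `exact_limit`.
#' @param exact_limit Feature-count cutoff for automatic exact mode.
#' @return A `shap_matrix`: `values` (n_samples x p x n_classes array),
#'   `base` (per-class mean background prediction), `features`,
#'   `classes`, `mode`.
#' @export
shapley_values <- function(predict_fn, background, samples,
                           n_permutations = 100L, seed = 1L,
                           exact = NULL, exact_limit = 8L) {
  B <- as.matrix(background); Xs <- as.matrix(samples)
  if (nrow(B) == 0L) stop("background must be non-empty")
  if (ncol(B) != ncol(Xs)) stop("feature count mismatch")
  p <- ncol(B)
  if (is.null(exact)) exact <- p <= exact_limit
  base_pred <- predict_fn(B)
  if (is.null(dim(base_pred))) base_pred <- matrix(base_pred, ncol = 1L)
  n_classes <- ncol(base_pred)
  classes <- colnames(base_pred)
  if (is.null(classes)) classes <- paste0("class", seq_len(n_classes))
  base <- colMeans(base_pred)
  n <- nrow(Xs)
  phi <- array(0, dim = c(n, p, n_classes),
               dimnames = list(NULL, colnames(B), classes))
  eval_fn <- function(M, i) {
    out <- tryCatch(predict_fn(M), error = function(e)
      stop("predict_fn failed while explaining sample ", i, ": ",
           conditionMessage(e)))
    if (is.null(dim(out))) matrix(out, ncol = 1L) else out
  }
  if (exact) {
    n_sub <- 2L^p
    masks <- matrix(FALSE, n_sub, p)
    for (f in seq_len(p))
      masks[, f] <- bitwAnd(0:(n_sub - 1L), bitwShiftL(1L, f - 1L)) > 0L
    sizes <- rowSums(masks)
    # Shapley kernel weight of the coalition *below* feature addition;
    # the full coalition never plays that role, so leave its weight 0
    w <- numeric(n_sub)
    part <- sizes < p
    w[part] <- factorial(sizes[part]) *
      factorial(p - sizes[part] - 1) / factorial(p)
    nb <- nrow(B)
    for (i in seq_len(n)) {
      # one prediction batch: every (coalition, background row) hybrid
      big <- B[rep(seq_len(nb), times = n_sub), , drop = FALSE]
      smask <- masks[rep(seq_len(n_sub), each = nb), , drop = FALSE]
      xrep <- matrix(Xs[i, ], nrow(big), p, byrow = TRUE)
      big[smask] <- xrep[smask]
      pred <- eval_fn(big, i)
      grp <- rep(seq_len(n_sub), each = nb)
      v <- apply(pred, 2, function(col) tapply(col, grp, mean))
      v <- matrix(v, n_sub, n_classes)
      for (f in seq_len(p)) {
        with_f <- masks[, f]
        # pair S (without f) with S + f: same mask plus bit f
        idx_without <- which(!with_f)
        idx_with <- idx_without + 2L^(f - 1L)
        contrib <- w[idx_without] *
          (v[idx_with, , drop = FALSE] - v[idx_without, , drop = FALSE])
        phi[i, f, ] <- colSums(contrib)
      }
    }
  } else {
    withr::with_seed(seed, {
      nb <- nrow(B)
      for (i in seq_len(n)) {
        acc <- matrix(0, p, n_classes)
        for (perm in seq_len(n_permutations)) {
          ord <- sample.int(p)
          b <- B[sample.int(nb, 1L), ]
          # walk the permutation, swapping in the sample's features
          hyb <- matrix(b, p + 1L, p, byrow = TRUE)
          for (step in seq_len(p)) {
            f_on <- ord[seq_len(step)]
            hyb[step + 1L, f_on] <- Xs[i, f_on]
          }
          colnames(hyb) <- colnames(B)
          pred <- eval_fn(hyb, i)
          d <- pred[-1L, , drop = FALSE] - pred[-(p + 1L), , drop = FALSE]
          acc[ord, ] <- acc[ord, ] + d
        }
        phi[i, , ] <- acc / n_permutations
      }
    })
  }
  structure(list(values = phi, base = stats::setNames(base, classes),
                 features = colnames(B), classes = classes,
                 mode = if (exact) "exact" else "sampling"),
            class = "shap_matrix")
}

#' Global feature importance from Shapley values
#'
#' Mean absolute attribution over all samples and classes per feature,
#' in descending order -- the data behind a cumulative importance plot.
#'
#' @param shap A `shap_matrix`.
#' @return Named numeric vector, sorted descending.
#' @export
global_importance <- function(shap) {
  imp <- apply(abs(shap$values), 2, mean)
  names(imp) <- shap$features
  sort(imp, decreasing = TRUE)
}

#' Beeswarm-plot export for one class
#'
#' Long-format table of per-sample attributions for the given class,
#' with the raw feature values for color mapping; features ordered by
#' the sum of absolute attributions (largest first).
#'
#' @param shap A `shap_matrix`. @param X The explained feature rows.
#' @param class Class name or index.
#' @return data.frame: `feature`, `sample`, `phi`, `value`.
#' @export
beeswarm_export <- function(shap, X, class) {
  X <- as.matrix(X)
  if (is.character(class)) class <- match(class, shap$classes)
  if (is.na(class) || class < 1 || class > length(shap$classes))
    stop("invalid class")
  V <- shap$values[, , class, drop = FALSE]
  dim(V) <- dim(shap$values)[1:2]
  ord <- order(colSums(abs(V)), decreasing = TRUE)
  n <- nrow(V)
  do.call(rbind, lapply(ord, function(f)
    data.frame(feature = shap$features[f], sample = seq_len(n),
               phi = V[, f], value = X[, shap$features[f]],
               row.names = NULL, stringsAsFactors = FALSE)))
}
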