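#' Local outlier factor scores
#'
#' Classic LOF (density-ratio anomaly score) with Euclidean distances:
#' for each point, the k-distance neighborhood (including all points
#' tied at the k-th distance), reachability distances, local
#' reachability density, and finally the ratio of the neighbors' mean
#' density to the point's own. Interior points of a homogeneous cloud
#' score near 1; isolated points score well above 1.
#'
#' The full distance matrix is materialized, so memory is O(n^2);
#' adequate for the few-thousand-sample tables this pipeline produces.
#'
#' @param X Numeric matrix or data.frame of features (rows = samples).
#' @param k Neighbor count (default 20).
#' @return A `lof_result`: `scores` (length n), `k`.
#' @export
lof_scores <- function(X, k = 20L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("need more samples than neighbors (n > k)")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  # k-distance with standard ties rule: neighborhood = all points within
  # the k-th smallest distance
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- D[i, ]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    o <- nbrs[[i]]
    reach <- pmax(kdist[o], D[i, o])
    lrd[i] <- if (all(reach == 0)) Inf else length(o) / sum(reach)
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    o <- nbrs[[i]]
    scores[i] <- if (is.infinite(lrd[i])) {
      if (all(is.infinite(lrd[o]))) 1 else 0
    } else mean(lrd[o]) / lrd[i]
  }
  structure(list(scores = scores, k = as.integer(k)), class = "lof_result")
}

#' Remove the most anomalous training samples by LOF
#'
#' Drops `floor(fraction * n)` rows. Under the default convention
#' (`convention = "anomalous"`) the rows with the highest LOF scores --
#' i.e. the lowest-density samples -- are removed, which is the
#' behavior of libraries whose LOF score is negated (lower = more
#' anomalous). `convention = "literal_lowest"` removes the lowest raw
#' LOF scores instead. Ties are broken by row order, so the result is
#' deterministic.
#'
#' @param X Feature matrix/data.frame (training rows only).
#' @param fraction Fraction to remove, in \[0, 1).
#' @param k LOF neighbor count.
#' @param convention `"anomalous"` (default) or `"literal_lowest"`.
#' @return List: `kept` (row indices kept), `removed`, `lof` (scores).
#' @export
remove_outliers <- function(X, fraction = 0.10, k = 20L,
                            convention = c("anomalous", "literal_lowest")) {
  convention <- match.arg(convention)
  X <- as.matrix(X)
  n <- nrow(X)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_drop <- floor(fraction * n)
  if (n_drop == 0L)
    return(list(kept = seq_len(n), removed = integer(0), lof = NULL))
  res <- lof_scores(X, k = k)
  s <- res$scores
  ord <- if (convention == "anomalous")
    order(-s, seq_along(s)) else order(s, seq_along(s))
  removed <- sort(ord[seq_len(n_drop)])
  list(kept = setdiff(seq_len(n), removed), removed = removed, lof = res)
}

#' Collinearity filter at |PCC| >= threshold
#'
#' Computes the Pearson correlation matrix of the training features,
#' then repeatedly takes the first violating pair in lexicographic
#' upper-triangle order, removes one member uniformly at random
#' (seeded), and re-examines the surviving set, until no pair reaches
#' the threshold. Constant (zero-variance) features are dropped first
#' with a warning.
#'
#' @param X Feature matrix/data.frame with column names.
#' @param threshold Absolute PCC threshold (default 0.9).
#' @param seed Integer seed for the random member choice.
#' @return A `feature_mask`: `kept` (names), `dropped` (names),
#'   `pairs` (data.frame of examined violations), `threshold`, `seed`.
#' @export
collinearity_filter <- function(X, threshold = 0.9, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("dropping constant features: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  cm <- abs(stats::cor(X))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(cm))
  names(alive) <- colnames(cm)
  log_pairs <- list()
  withr::with_seed(seed, {
    repeat {
      sub <- cm[alive, alive, drop = FALSE]
      viol <- which(upper.tri(sub) & sub >= threshold, arr.ind = TRUE)
      if (nrow(viol) == 0L) break
      viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
      a <- rownames(sub)[viol[1, 1]]
      b <- colnames(sub)[viol[1, 2]]
      drop <- if (stats::runif(1) < 0.5) a else b
      alive[drop] <- FALSE
      log_pairs[[length(log_pairs) + 1L]] <-
        data.frame(f1 = a, f2 = b, pcc = sub[viol[1, 1], viol[1, 2]],
                   dropped = drop, stringsAsFactors = FALSE)
    }
  })
  kept <- names(alive)[alive]
  structure(list(kept = kept,
                 dropped = c(colnames(cm)[!alive],
                             setdiff(names(sds)[const], character(0))),
                 pairs = if (length(log_pairs))
                   do.call(rbind, log_pairs) else NULL,
                 threshold = threshold, seed = seed),
            class = "feature_mask")
}
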