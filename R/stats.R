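#' Per-drug gray-level probability distributions
#'
#' Pools the pixel values of every image of each drug (expected to be
#' normalized/standardized 0..255 images) into an empirical probability
#' distribution over the 256 gray levels, aligned across drugs.
#'
#' @param images_by_drug Named list: one list of image matrices per drug.
#' @return A `gray_level_distribution`: `prob` (256 x n_drugs matrix,
#'   columns sum to 1), `n_pixels` per drug, `levels` (0..255).
#' @export
gray_level_distributions <- function(images_by_drug) {
  stopifnot(length(images_by_drug) >= 1, !is.null(names(images_by_drug)))
  prob <- sapply(images_by_drug, function(imgs) {
    if (length(imgs) == 0L) stop("at least one image per drug required")
    px <- unlist(lapply(imgs, function(im)
      as.integer(round(pmin(pmax(im, 0), 255)))))
    tabulate(px + 1L, nbins = 256L) / length(px)
  })
  structure(list(prob = prob,
                 n_pixels = vapply(images_by_drug, function(imgs)
                   sum(vapply(imgs, length, integer(1))), numeric(1)),
                 levels = 0:255),
            class = "gray_level_distribution")
}

#' Kolmogorov-Smirnov distance between two gray-level distributions
#' @param dist A `gray_level_distribution`. @param a,b Drug names/indices.
#' @return Max absolute CDF difference.
#' @export
gld_ks_distance <- function(dist, a, b) {
  max(abs(cumsum(dist$prob[, a]) - cumsum(dist$prob[, b])))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance:
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom.
#' Zero within-group variance with unequal group means yields F = Inf,
#' p = 0; fully degenerate input (all values equal) yields F = 0.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List: `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs >= 2 values")
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  gm <- sum(n * means) / N
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L; dfw <- N - k
  msb <- ssb / dfb; msw <- ssw / dfw
  if (msw == 0) {
    if (msb == 0) return(list(F = 0, p = 1, df_between = dfb,
                              df_within = dfw))
    return(list(F = Inf, p = 0, df_between = dfb, df_within = dfw))
  }
  Fst <- msb / msw
  list(F = Fst, p = stats::pf(Fst, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparison of group means using the studentized range
#' distribution with the pooled within-group variance (Tukey-Kramer
#' standard error for unequal group sizes). p-values come from
#' `ptukey`, which integrates the range distribution numerically.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param alpha Significance level for the `reject` column (default 0.01).
#' @return data.frame: `group1`, `group2`, `diff`, `se`, `q`, `p`,
#'   `reject`.
#' @export
tukey_hsd <- function(groups, alpha = 0.01) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  dfw <- sum(n) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / dfw
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    d <- means[j] - means[i]
    q <- if (se > 0) abs(d) / se else if (d == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], diff = d, se = se, q = q, p = p,
      reject = p < alpha, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Gray-level distribution statistics for a dataset
#'
#' Groups the normalized images by drug, forms the pooled gray-level
#' distributions, and tests for mean differences with one-way ANOVA and
#' Tukey HSD. The unit of observation defaults to per-image mean
#' standardized intensity (`unit = "image"`); `unit = "pixel"` pools
#' raw pixels, which inflates the degrees of freedom enormously and is
#' provided for comparability only.
#'
#' @param ds A `speckle_dataset` of normalized images.
#' @param unit `"image"` or `"pixel"`. @param alpha Significance level.
#' @return List: `distributions`, `anova`, `tukey`, `unit`.
#' @export
distribution_stats <- function(ds, unit = c("image", "pixel"),
                               alpha = 0.01) {
  unit <- match.arg(unit)
  drugs <- unique(ds$meta$drug)
  by_drug <- lapply(drugs, function(d) ds$images[ds$meta$drug == d])
  names(by_drug) <- drugs
  gld <- gray_level_distributions(by_drug)
  groups <- lapply(by_drug, function(imgs) {
    if (unit == "image") vapply(imgs, function(im) mean(im), numeric(1))
    else as.numeric(unlist(imgs))
  })
  list(distributions = gld, anova = anova_oneway(groups),
       tukey = tukey_hsd(groups, alpha = alpha), unit = unit)
}
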