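#' First-order gray-level statistics
#'
#' Mean intensity, population standard deviation and variance, Fisher
#' (excess) kurtosis and skewness of the image gray levels. Skewness and
#' kurtosis of a constant image are defined as 0.
#'
#' @param image 2-D numeric matrix.
#' @return Named numeric vector of length 5: `intensity`,
#'   `standard_deviation`, `variance`, `kurtosis`, `skewness`.
#' @export
first_order_stats <- function(image) {
  x <- as.numeric(image)
  if (length(x) == 0L) stop("empty image")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    sk <- mean((x - m)^3) / v^1.5
    ku <- mean((x - m)^4) / v^2 - 3
  } else sk <- ku <- 0
  c(intensity = m, standard_deviation = sqrt(v), variance = v,
    kurtosis = ku, skewness = sk)
}

glcm_offset <- function(theta) {
  # (delta_row, delta_col), rows increasing downward
  switch(as.character(theta),
         "0" = c(0L, 1L), "45" = c(-1L, 1L),
         "90" = c(-1L, 0L), "135" = c(-1L, -1L),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels at displacement `d` along
#' direction `theta` (degrees). The matrix is kept asymmetric (a single
#' offset per direction, no transpose symmetrization); pairs with either
#' endpoint outside the image are skipped. Offsets, with rows increasing
#' downward: 0 deg (0,+1), 45 deg (-1,+1), 90 deg (-1,0),
#' 135 deg (-1,-1).
#'
#' @param image 2-D matrix with integer gray levels in `0..(n_levels-1)`.
#' @param d Displacement (>= 1). @param theta Direction in degrees.
#' @param n_levels Number of gray levels K (default 256, full 8 bit).
#' @return A `glcm` object: `counts` (K x K integer), `p` (normalized),
#'   `d`, `theta`, `n_levels`.
#' @export
compute_glcm <- function(image, d = 1L, theta = 0, n_levels = 256L) {
  if (d < 1) stop("d must be >= 1")
  off <- glcm_offset(theta) * as.integer(d)
  img <- image
  if (min(img) < 0 || max(img) > n_levels - 1)
    stop("gray levels outside 0..(n_levels-1)")
  h <- nrow(img); w <- ncol(img)
  r <- seq_len(h); cidx <- seq_len(w)
  r1 <- r[r + off[1] >= 1 & r + off[1] <= h]
  c1 <- cidx[cidx + off[2] >= 1 & cidx + off[2] <= w]
  K <- as.integer(n_levels)
  if (length(r1) == 0L || length(c1) == 0L) {
    counts <- matrix(0L, K, K)
  } else {
    i <- img[r1, c1, drop = FALSE]
    j <- img[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- matrix(tabulate(as.integer(i) * K + as.integer(j) + 1L,
                              nbins = K * K),
                     K, K, byrow = TRUE)
  }
  tot <- sum(counts)
  structure(list(counts = counts,
                 p = if (tot > 0) counts / tot else counts,
                 d = as.integer(d), theta = theta, n_levels = K),
            class = "glcm")
}

glcm_stat_names <- c(
  "energy", "contrast", "correlation", "sum_of_squares_variance",
  "homogeneity", "sum_average", "sum_variance", "sum_entropy", "entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2",
  "dissimilarity", "autocorrelation", "cluster_shade",
  "cluster_prominence", "maximum_probability", "inverse_difference",
  "idmn")

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Haralick-style statistics of a co-occurrence matrix
#'
#' Computes 20 scalar texture measures from the normalized GLCM: the
#' Haralick set (energy/ASM, contrast, correlation, sum-of-squares
#' variance, homogeneity/IDM, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, information
#' measures of correlation 1 and 2) plus dissimilarity, autocorrelation,
#' cluster shade, cluster prominence, maximum probability, inverse
#' difference, and inverse difference moment normalized. Entropies use
#' the natural log with the 0 log 0 = 0 convention; correlation of a
#' degenerate (zero marginal variance) matrix is 0, as are the
#' information measures when a marginal entropy vanishes.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Named numeric vector of length 20.
#' @export
glcm_stats <- function(glcm) {
  P <- glcm$p
  if (sum(glcm$counts) == 0) stop("empty GLCM (no valid pixel pairs)")
  K <- glcm$n_levels
  lev <- 0:(K - 1)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  II <- matrix(lev, K, K)            # row level i
  JJ <- matrix(lev, K, K, byrow = TRUE)
  DIF <- II - JJ
  # p_{x+y}(k), k = 0..2K-2 and p_{x-y}(k), k = 0..K-1
  psum <- as.numeric(tapply(P, factor(II + JJ, levels = 0:(2 * K - 2)), sum))
  psum[is.na(psum)] <- 0
  pdif <- as.numeric(tapply(P, factor(abs(DIF), levels = lev), sum))
  pdif[is.na(pdif)] <- 0
  ks <- 0:(2 * K - 2); kd <- lev
  sa <- sum(ks * psum)
  mu_d <- sum(kd * pdif)
  hx <- entropy_nat(px); hy <- entropy_nat(py); hxy <- entropy_nat(P)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log(pxpy[pos]))
  pos2 <- pxpy > 0
  hxy2 <- -sum(pxpy[pos2] * log(pxpy[pos2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 0 && sy > 0)
    (sum(II * JJ * P) - mux * muy) / (sx * sy) else 0
  c(energy = sum(P^2),
    contrast = sum(DIF^2 * P),
    correlation = corr,
    sum_of_squares_variance = sum((II - mux)^2 * P),
    homogeneity = sum(P / (1 + DIF^2)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = entropy_nat(psum),
    entropy = hxy,
    difference_variance = sum((kd - mu_d)^2 * pdif),
    difference_entropy = entropy_nat(pdif),
    imc1 = imc1,
    imc2 = imc2,
    dissimilarity = sum(abs(DIF) * P),
    autocorrelation = sum(II * JJ * P),
    cluster_shade = sum((II + JJ - mux - muy)^3 * P),
    cluster_prominence = sum((II + JJ - mux - muy)^4 * P),
    maximum_probability = max(P),
    inverse_difference = sum(P / (1 + abs(DIF))),
    idmn = sum(P / (1 + DIF^2 / K^2)))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal (quantized) gray level along every line
#' of direction `theta`. Gray levels are uniformly quantized from 256 to
#' `n_levels` bins first: on speckle images full 8-bit runs are almost
#' all of length one, which destroys the run statistics.
#'
#' @param image 2-D matrix, integer gray levels 0..255.
#' @param theta Direction in degrees (0, 45, 90, 135).
#' @param n_levels Number of quantized gray levels (default 32).
#' @return A `glrlm` object: `counts` (L x R, R = max run length),
#'   `theta`, `n_levels`, `n_pixels`.
#' @export
compute_glrlm <- function(image, theta = 0, n_levels = 32L) {
  glcm_offset(theta)  # validates theta
  h <- nrow(image); w <- ncol(image)
  q <- floor(image / (256 / n_levels))
  q <- pmin(pmax(q, 0), n_levels - 1)
  lines <- switch(as.character(theta),
    "0" = split(q, row(q)),
    "90" = split(q, col(q)),
    "45" = split(q, row(q) + col(q)),        # anti-diagonals
    "135" = split(q, row(q) - col(q)))       # main diagonals
  # split() on row(q)+col(q) groups in matrix column order, which walks
  # each diagonal in consecutive spatial order, so rle() sees true runs
  L <- as.integer(n_levels); R <- max(h, w)
  counts <- matrix(0L, L, R)
  for (ln in lines) {
    rl <- rle(as.integer(ln))
    idx <- (rl$lengths - 1L) * L + rl$values + 1L
    tb <- tabulate(idx, nbins = L * R)
    counts <- counts + matrix(tb, L, R)
  }
  structure(list(counts = counts, theta = theta, n_levels = L,
                 n_pixels = h * w),
            class = "glrlm")
}

glrlm_stat_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                      "srlge", "srhge", "lrlge", "lrhge")

#' Run-length texture statistics
#'
#' The eleven standard run-emphasis measures (Galloway/Chu): short- and
#' long-run emphasis, gray-level and run-length non-uniformity, run
#' percentage, low/high gray-level run emphasis, and the four joint
#' short/long x low/high emphases. Gray levels are indexed 1..L (the
#' quantized level plus one) so the low-gray-level weights are defined.
#'
#' @param glrlm A [compute_glrlm()] result.
#' @return Named numeric vector of length 11.
#' @export
glrlm_stats <- function(glrlm) {
  M <- glrlm$counts
  nr <- sum(M)
  if (nr == 0) stop("GLRLM contains no runs")
  L <- nrow(M); R <- ncol(M)
  gl <- matrix(seq_len(L), L, R)          # 1-based gray level index
  rl <- matrix(seq_len(R), L, R, byrow = TRUE)
  c(sre = sum(M / rl^2) / nr,
    lre = sum(M * rl^2) / nr,
    gln = sum(rowSums(M)^2) / nr,
    rln = sum(colSums(M)^2) / nr,
    rp = nr / glrlm$n_pixels,
    lgre = sum(M / gl^2) / nr,
    hgre = sum(M * gl^2) / nr,
    srlge = sum(M / (gl^2 * rl^2)) / nr,
    srhge = sum(M * gl^2 / rl^2) / nr,
    lrlge = sum(M * rl^2 / gl^2) / nr,
    lrhge = sum(M * gl^2 * rl^2) / nr)
}

speckle_thetas <- c(0, 45, 90, 135)

#' Names of the 129 features, in extraction order
#' @return Character vector of length 129.
#' @export
feature_names <- function() {
  c(names(first_order_stats(matrix(0, 2, 2))),
    as.vector(vapply(speckle_thetas, function(th)
      paste0(glcm_stat_names, "_", th), character(20))),
    as.vector(vapply(speckle_thetas, function(th)
      paste0(glrlm_stat_names, "_", th), character(11))))
}

#' Extract the full 129-feature descriptor of one image
#'
#' Concatenates the 5 first-order statistics, the 20 co-occurrence
#' statistics for each of the four directions (d = 1, full 256 gray
#' levels), and the 11 run-length statistics for each direction
#' (32 quantized levels): 5 + 4 x 20 + 4 x 11 = 129 values. Input pixels
#' are rounded and clamped to the integer 0..255 range first.
#'
#' @param image 2-D numeric matrix (8-bit scale).
#' @param d GLCM displacement. @param glrlm_levels GLRLM quantization.
#' @return Named numeric vector of length 129.
#' @export
extract_features <- function(image, d = 1L, glrlm_levels = 32L) {
  if (length(dim(image)) != 2L) stop("image must be a 2-D matrix")
  img <- round(pmin(pmax(image, 0), 255))
  storage.mode(img) <- "integer"
  fo <- first_order_stats(img)
  gc <- lapply(speckle_thetas, function(th)
    glcm_stats(compute_glcm(img, d = d, theta = th)))
  gr <- lapply(speckle_thetas, function(th)
    glrlm_stats(compute_glrlm(img, theta = th, n_levels = glrlm_levels)))
  out <- c(fo, unlist(gc), unlist(gr))
  names(out) <- feature_names()
  out
}

#' Extract the feature table of a whole dataset
#'
#' @param ds A `speckle_dataset` (typically normalized crops).
#' @param ... Passed to [extract_features()].
#' @return data.frame: `drug`, `sample_id`, `video_id`, `frame_index`,
#'   `day`, then the 129 feature columns.
#' @export
extract_feature_table <- function(ds, ...) {
  X <- t(vapply(ds$images, extract_features, numeric(129), ...))
  cbind(ds$meta, as.data.frame(X))
}
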