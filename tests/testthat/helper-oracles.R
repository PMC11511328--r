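# Independent brute-force oracles. These deliberately use naive
# per-element loops and direct textbook formulas, structured differently
# from the package implementations they are checked against.

oracle_glcm_counts <- function(img, d, theta, n_levels = 256L) {
  off <- switch(as.character(theta),
                "0" = c(0L, 1L), "45" = c(-1L, 1L),
                "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  off <- off * d
  K <- n_levels
  counts <- matrix(0L, K, K)
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
      i <- img[r, cc]; j <- img[r2, c2]
      counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1L
    }
  }
  counts
}

# All 20 statistics by direct summation over the nonzero entries of P
# (terms with P = 0 contribute nothing, including to entropies).
oracle_glcm_stats <- function(counts) {
  K <- nrow(counts)
  P <- counts / sum(counts)
  nz <- which(P > 0, arr.ind = TRUE)
  px <- rowSums(P); py <- colSums(P)
  lev <- 0:(K - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  psum <- rep(0, 2 * K - 1); pdif <- rep(0, K)
  energy <- contrast <- diss <- homog <- entropy <- autoc <- 0
  ssv <- shade <- promin <- id <- idmn <- corr_num <- 0
  for (r in seq_len(nrow(nz))) {
    i <- unname(nz[r, 1]) - 1; j <- unname(nz[r, 2]) - 1
    p <- P[i + 1, j + 1]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    diss <- diss + abs(i - j) * p
    homog <- homog + p / (1 + (i - j)^2)
    entropy <- entropy - p * log(p)
    autoc <- autoc + i * j * p
    ssv <- ssv + (i - mux)^2 * p
    shade <- shade + (i + j - mux - muy)^3 * p
    promin <- promin + (i + j - mux - muy)^4 * p
    id <- id + p / (1 + abs(i - j))
    idmn <- idmn + p / (1 + (i - j)^2 / K^2)
    corr_num <- corr_num + (i - mux) * (j - muy) * p
    psum[i + j + 1] <- psum[i + j + 1] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  ent0 <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  ks <- 0:(2 * K - 2); kd <- lev
  sa <- sum(ks * psum)
  hx <- ent0(px); hy <- ent0(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy2 <- hxy2 - q * log(q)
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(q)
    }
  }
  c(energy = energy,
    contrast = contrast,
    correlation = if (sx > 0 && sy > 0) corr_num / (sx * sy) else 0,
    sum_of_squares_variance = ssv,
    homogeneity = homog,
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = ent0(psum),
    entropy = entropy,
    difference_variance = sum((kd - sum(kd * pdif))^2 * pdif),
    difference_entropy = ent0(pdif),
    imc1 = if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy)))),
    dissimilarity = diss,
    autocorrelation = autoc,
    cluster_shade = shade,
    cluster_prominence = promin,
    maximum_probability = max(P),
    inverse_difference = id,
    idmn = idmn)
}

# Run enumeration by explicitly walking every line of the direction.
oracle_glrlm_counts <- function(img, theta, n_levels = 32L) {
  q <- pmin(pmax(floor(img / (256 / n_levels)), 0), n_levels - 1)
  h <- nrow(q); w <- ncol(q)
  step <- switch(as.character(theta),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(1L, 0L), "135" = c(1L, 1L))
  starts <- switch(as.character(theta),
    "0" = lapply(seq_len(h), function(r) c(r, 1L)),
    "90" = lapply(seq_len(w), function(cc) c(1L, cc)),
    "45" = c(lapply(seq_len(h), function(r) c(r, 1L)),
             lapply(2:max(w, 2), function(cc) c(h, cc))[seq_len(w - 1)]),
    "135" = c(lapply(seq_len(w), function(cc) c(1L, cc)),
              lapply(2:max(h, 2), function(r) c(r, 1L))[seq_len(h - 1)]))
  L <- n_levels; R <- max(h, w)
  counts <- matrix(0L, L, R)
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur <- NA; len <- 0L
    while (r >= 1 && r <= h && cc >= 1 && cc <= w) {
      v <- q[r, cc]
      if (!is.na(cur) && v == cur) len <- len + 1L
      else {
        if (!is.na(cur))
          counts[cur + 1L, len] <- counts[cur + 1L, len] + 1L
        cur <- v; len <- 1L
      }
      r <- r + step[1]; cc <- cc + step[2]
    }
    if (!is.na(cur)) counts[cur + 1L, len] <- counts[cur + 1L, len] + 1L
  }
  counts
}

oracle_glrlm_stats <- function(counts, n_pixels) {
  nr <- sum(counts)
  L <- nrow(counts); R <- ncol(counts)
  acc <- stats::setNames(rep(0, 11),
    c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge",
      "srhge", "lrlge", "lrhge"))
  for (i in seq_len(L)) for (j in seq_len(R)) {
    m <- counts[i, j]
    if (m == 0) next
    acc["sre"] <- acc["sre"] + m / j^2
    acc["lre"] <- acc["lre"] + m * j^2
    acc["lgre"] <- acc["lgre"] + m / i^2
    acc["hgre"] <- acc["hgre"] + m * i^2
    acc["srlge"] <- acc["srlge"] + m / (i^2 * j^2)
    acc["srhge"] <- acc["srhge"] + m * i^2 / j^2
    acc["lrlge"] <- acc["lrlge"] + m * j^2 / i^2
    acc["lrhge"] <- acc["lrhge"] + m * i^2 * j^2
  }
  acc["gln"] <- sum(sapply(seq_len(L), function(i) sum(counts[i, ]))^2)
  acc["rln"] <- sum(sapply(seq_len(R), function(j) sum(counts[, j]))^2)
  out <- acc / nr
  out["rp"] <- nr / n_pixels
  out
}

# Textbook LOF, one point at a time, O(n^2) with explicit sorting.
oracle_lof <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(a, b) sqrt(sum((X[a, ] - X[b, ])^2))
  kdist <- numeric(n); neigh <- vector("list", n)
  for (p in seq_len(n)) {
    ds <- sapply(setdiff(seq_len(n), p), function(o) d(p, o))
    others <- setdiff(seq_len(n), p)
    kd <- sort(ds)[k]
    kdist[p] <- kd
    neigh[[p]] <- others[ds <= kd]
  }
  lrd <- sapply(seq_len(n), function(p) {
    rd <- sapply(neigh[[p]], function(o) max(kdist[o], d(p, o)))
    length(neigh[[p]]) / sum(rd)
  })
  sapply(seq_len(n), function(p) mean(lrd[neigh[[p]]]) / lrd[p])
}

random_image <- function(h = 16, w = 16, levels = 0:255) {
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}
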