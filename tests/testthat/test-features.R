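# Texture descriptor: first-order statistics, GLCM, GLRLM, and the
# assembled 129-feature vector, checked against brute-force oracles.

test_that("first-order statistics match hand arithmetic", {
  expect_equal(first_order_stats(matrix(100, 3, 3)),
               c(intensity = 100, standard_deviation = 0, variance = 0,
                 kurtosis = 0, skewness = 0))
  two <- matrix(c(0, 0, 255, 255), 2, 2)
  fo <- first_order_stats(two)
  expect_equal(unname(fo["intensity"]), 127.5)
  expect_equal(unname(fo["variance"]), 16256.25)
  expect_equal(unname(fo["skewness"]), 0)
  # permutation invariance: checkerboard has the same first-order stats
  cb <- matrix(c(0, 255), 8, 8)
  expect_equal(unname(first_order_stats(cb)[c("intensity", "variance")]),
               c(127.5, 16256.25))
})

test_that("GLCM counts: offsets, totals and tiny examples", {
  cst <- matrix(7L, 4, 4)
  g <- compute_glcm(cst, theta = 0)
  expect_equal(sum(g$counts), 4 * 3)
  expect_equal(g$counts[8, 8], 12L)
  expect_equal(sum(g$p), 1)
  tiny <- matrix(c(0L, 2L, 1L, 3L), 2, 2)  # [[0,1],[2,3]] row-wise
  g0 <- compute_glcm(tiny, theta = 0)
  expect_equal(g0$counts[1, 2], 1L)  # (0,1)
  expect_equal(g0$counts[3, 4], 1L)  # (2,3)
  expect_equal(sum(g0$counts), 2)
  # closed-form pair totals for every direction and odd sizes
  img <- random_image(7, 5)
  expect_equal(sum(compute_glcm(img, theta = 0)$counts), 7 * 4)
  expect_equal(sum(compute_glcm(img, theta = 90)$counts), 6 * 5)
  expect_equal(sum(compute_glcm(img, theta = 45)$counts), 6 * 4)
  expect_equal(sum(compute_glcm(img, theta = 135)$counts), 6 * 4)
  expect_error(compute_glcm(img, theta = 30), "theta")
})

test_that("GLCM statistics: constant and checkerboard closed forms", {
  s_const <- glcm_stats(compute_glcm(matrix(5L, 6, 6), theta = 0))
  expect_equal(unname(s_const[c("energy", "entropy", "contrast",
                                "dissimilarity",
                                "maximum_probability")]),
               c(1, 0, 0, 0, 1))
  cb <- matrix(rep_len(c(0L, 255L), 25), 5, 5)  # checkerboard (odd side)
  s_cb <- glcm_stats(compute_glcm(cb, theta = 0))
  expect_equal(unname(s_cb["contrast"]), 255^2)
  expect_equal(unname(s_cb["dissimilarity"]), 255)
  expect_equal(unname(s_cb["entropy"]), log(2))
  expect_equal(unname(s_cb["energy"]), 0.5)
})

test_that("GLCM counts and all 20 statistics match the brute-force
           oracle on random images", {
  set.seed(101)
  for (rep in 1:25) for (th in c(0, 45, 90, 135)) {
    img <- random_image(16, 16)
    g <- compute_glcm(img, theta = th)
    oc <- oracle_glcm_counts(img, 1L, th)
    expect_identical(g$counts, oc)
    expect_equal(glcm_stats(g), oracle_glcm_stats(oc), tolerance = 1e-10)
  }
})

test_that("GLRLM: constant image, manual runs, pixel conservation", {
  cst <- matrix(200L, 5, 5)
  g <- compute_glrlm(cst, theta = 0)
  lev <- floor(200 / 8) + 1
  expect_equal(g$counts[lev, 5], 5L)
  expect_equal(sum(g$counts), 5L)
  row_img <- matrix(c(0L, 0L, 8L, 8L, 8L), 1, 5)  # levels 0,0,1,1,1
  r <- compute_glrlm(row_img, theta = 0)
  expect_equal(r$counts[1, 2], 1L)
  expect_equal(r$counts[2, 3], 1L)
  set.seed(11)
  for (rep in 1:5) for (th in c(0, 45, 90, 135)) {
    img <- random_image(9, 13, levels = 0:31 * 8)
    g <- compute_glrlm(img, theta = th)
    rl <- matrix(seq_len(ncol(g$counts)), nrow(g$counts),
                 ncol(g$counts), byrow = TRUE)
    expect_equal(sum(g$counts * rl), 9 * 13)
  }
})

test_that("GLRLM statistics: closed forms and oracle equivalence", {
  sc <- glrlm_stats(compute_glrlm(matrix(16L, 8, 8), theta = 0))
  expect_equal(unname(sc[c("sre", "lre", "rp")]),
               c(1 / 64, 64, 1 / 8))
  alt <- matrix(rep_len(c(0L, 32L), 25), 5, 5)  # all runs length 1
  sa <- glrlm_stats(compute_glrlm(alt, theta = 0))
  expect_equal(unname(sa[c("sre", "lre", "rp")]), c(1, 1, 1))
  set.seed(22)
  for (rep in 1:25) for (th in c(0, 45, 90, 135)) {
    img <- random_image(16, 16)
    g <- compute_glrlm(img, theta = th)
    oc <- oracle_glrlm_counts(img, th)
    expect_identical(unname(g$counts), unname(oc))
    expect_equal(glrlm_stats(g),
                 oracle_glrlm_stats(oc, 256), tolerance = 1e-10)
  }
})

test_that("feature vector has 129 unique finite names in fixed order", {
  nm <- feature_names()
  expect_length(nm, 129)
  expect_false(any(duplicated(nm)))
  img <- random_image(32, 32)
  f <- extract_features(img)
  expect_identical(names(f), nm)
  for (degenerate in list(matrix(0, 16, 16), matrix(255, 16, 16),
                          matrix(7, 16, 16)))
    expect_true(all(is.finite(extract_features(degenerate))))
})

test_that("90-degree rotation permutes the direction labels", {
  img <- random_image(12, 12)
  rot <- t(img)[nrow(img):1, ]  # counterclockwise 90 degrees
  g0 <- compute_glcm(img, theta = 0)$counts
  g45 <- compute_glcm(img, theta = 45)$counts
  g90 <- compute_glcm(img, theta = 90)$counts
  expect_identical(compute_glcm(rot, theta = 90)$counts, g0)
  expect_identical(compute_glcm(rot, theta = 135)$counts, g45)
  expect_identical(compute_glcm(rot, theta = 0)$counts, t(g90))
})

test_that("simulated speckle is directionally isotropic in its features", {
  # the d = 1 offset spans 1 px axially but sqrt(2) px diagonally, so
  # isotropy is checked within the equal-length direction pairs
  oc <- optical_config(frame_height_px = 256, frame_width_px = 256)
  img <- simulate_frame(0.6, sim_config(grain_size_px = 3), oc, seed = 33)
  f <- extract_features(img)
  reldiff <- function(a, b) abs(a - b) / abs((a + b) / 2)
  for (stat in c("contrast", "entropy", "dissimilarity", "homogeneity",
                 "sre", "lre", "rp", "gln")) {
    expect_lt(reldiff(f[paste0(stat, "_0")], f[paste0(stat, "_90")]),
              0.05)
    expect_lt(reldiff(f[paste0(stat, "_45")], f[paste0(stat, "_135")]),
              0.05)
  }
})
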