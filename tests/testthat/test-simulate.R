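# Simulator: optics arithmetic, brightness model, speckle statistics,
# temporal dynamics, dataset layout.

test_that("coherence length reproduces the instrument value and scales", {
  expect_equal(round(coherence_length_mm(optical_config()), 1), 2.2)
  expect_equal(coherence_length_mm(
    optical_config(wavelength_nm = 1000, linewidth_nm = 1)), 1.0)
  expect_equal(round(coherence_length_mm(
    optical_config(wavelength_nm = 658, linewidth_nm = 0.1)), 1), 4.3)
  expect_error(optical_config(wavelength_nm = 0), "wavelength")
  expect_error(optical_config(linewidth_nm = -1), "linewidth")
})

test_that("brightness factor: normalization, zeros, catalog ordering", {
  cat6 <- pan_drug_catalog()
  B <- vapply(cat6, brightness_factor, numeric(1), catalog = cat6)
  names(B) <- vapply(cat6, `[[`, character(1), "name")
  expect_equal(unname(max(B)), 1)
  # lipid-free drug scatters nothing
  d0 <- drug_spec("none", 0, 10, 10, 100)
  expect_equal(brightness_factor(d0, cat6), 0)
  # arithmetic oracle over the six catalog rows
  oracle <- vapply(cat6, function(d)
    d$lipids_g_per_L * (d$n_lipid - d$n_matrix)^2, numeric(1))
  expect_equal(unname(B), unname(oracle / max(oracle)), tolerance = 1e-12)
  # 40 g/L products outrank the 25 g/L product
  expect_gt(B[["OLIMEL N5E"]], B[["NUMETA G13E"]])
  expect_gt(B[["OLIMEL N7E"]], B[["NUMETA G13E"]])
  expect_error(brightness_factor(d0, list(d0)), "all-zero")
  # monotone in lipids and in delta-n
  b1 <- brightness_factor(drug_spec("a", 30, 0, 0, 0, n_matrix = 1.355), cat6)
  b2 <- brightness_factor(drug_spec("b", 35, 0, 0, 0, n_matrix = 1.355), cat6)
  b3 <- brightness_factor(drug_spec("c", 30, 0, 0, 0, n_matrix = 1.350), cat6)
  expect_gt(b2, b1)
  expect_gt(b3, b1)
})

test_that("catalog refractive indices span the stated ranges", {
  cat6 <- pan_drug_catalog()
  nm <- vapply(cat6, `[[`, numeric(1), "n_matrix")
  expect_equal(range(nm), c(1.349, 1.361))
  expect_true(all(vapply(cat6, function(d) d$n_lipid > d$n_matrix,
                         logical(1))))
})

oc512 <- optical_config(frame_height_px = 512, frame_width_px = 512)

test_that("single frames are fully developed speckle", {
  sc <- sim_config(grain_size_px = 3)
  expect_equal(simulate_frame(0, sc, oc512, seed = 1),
               matrix(0L, 512, 512))
  # contrast ~ 1 and exponential intensity, across independent seeds
  for (s in 1:5) {
    I <- simulate_frame(0.5, sc, oc512, seed = s, quantize = FALSE)
    expect_gt(sd(I) / mean(I), 0.95)
    expect_lt(sd(I) / mean(I), 1.05)
    ks <- suppressWarnings(
      stats::ks.test(as.numeric(I), "pexp", 1 / mean(I)))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

acov_halfwidth <- function(I) {
  # intensity autocovariance along x and y via FFT, half-max widths
  J <- I - mean(I)
  F <- stats::fft(J)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(J)
  ax <- ac[1, ]; ay <- ac[, 1]
  hw <- function(v) {
    v <- v / v[1]
    which(v < 0.5)[1] - 1
  }
  c(x = hw(ax), y = hw(ay))
}

test_that("grain size controls the autocovariance width, isotropically", {
  I3 <- simulate_frame(0.5, sim_config(grain_size_px = 3), oc512,
                       seed = 42, quantize = FALSE)
  I6 <- simulate_frame(0.5, sim_config(grain_size_px = 6), oc512,
                       seed = 42, quantize = FALSE)
  w3 <- acov_halfwidth(I3); w6 <- acov_halfwidth(I6)
  expect_gt(min(w6), max(w3))
  expect_lt(abs(w3["x"] - w3["y"]) / mean(w3), 0.10)
  expect_lt(abs(w6["x"] - w6["y"]) / mean(w6), 0.10)
})

test_that("mean gray level is monotone non-decreasing in B", {
  sc <- sim_config()
  means <- vapply(seq(0.1, 1, by = 0.1), function(B)
    mean(simulate_frame(B, sc, oc512, seed = 9)), numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("temporal mixing sets successive-frame correlation", {
  succ_cor <- function(eps, seed) {
    v <- simulate_video(0.5, 2, sim_config(temporal_mixing = eps),
                        oc512, seed = seed, quantize = FALSE)
    cor(as.numeric(v$frames[[1]]), as.numeric(v$frames[[2]]))
  }
  v0 <- simulate_video(0.5, 3, sim_config(temporal_mixing = 0), oc512,
                       seed = 5)
  expect_identical(v0$frames[[1]], v0$frames[[3]])
  expect_lt(abs(succ_cor(1, 2)), 0.05)
  r <- vapply(1:5, function(s) succ_cor(0.3, s), numeric(1))
  expect_true(all(abs(r - 0.7) < 0.05))
})

test_that("dataset layout, day tags and session gains behave", {
  oc <- optical_config(frame_height_px = 32, frame_width_px = 32)
  cat2 <- pan_drug_catalog()[1:2]
  ds <- build_dataset(cat2, samples_per_drug = 4, videos_per_sample = 2,
                      frames_per_video = 5, sim_config(), oc, seed = 3)
  expect_equal(length(ds), 2 * 4 * 2 * 5)
  expect_equal(unname(table(ds$meta$drug)), rep(4L * 2L * 5L, 2),
               ignore_attr = TRUE)
  # two samples on day 0, two on day 2, per drug
  per <- unique(ds$meta[, c("drug", "sample_id", "day")])
  expect_equal(unname(table(per$drug, per$day)),
               matrix(2L, 2, 2), ignore_attr = TRUE)
  ds1 <- build_dataset(cat2[1], 1, 1, 1, sim_config(), oc, seed = 3)
  expect_equal(length(ds1), 1L)
  # zero gain jitter: per-video mean intensities agree within 5% rel SD
  oc128 <- optical_config(frame_height_px = 128, frame_width_px = 128)
  ds0 <- build_dataset(cat2[1], samples_per_drug = 2,
                       videos_per_sample = 3, frames_per_video = 4,
                       sim_config(session_gain_sd = 0), oc128, seed = 8)
  vm <- tapply(vapply(ds0$images, mean, numeric(1)),
               paste(ds0$meta$sample_id, ds0$meta$video_id), mean)
  expect_lt(sd(vm) / mean(vm), 0.05)
})

test_that("datasets are reproducible per seed and frames per sub-seed", {
  oc <- optical_config(frame_height_px = 32, frame_width_px = 32)
  cat1 <- pan_drug_catalog()[1]
  d1 <- build_dataset(cat1, 1, 1, 3, sim_config(), oc, seed = 21)
  d2 <- build_dataset(cat1, 1, 1, 3, sim_config(), oc, seed = 21)
  expect_identical(d1$images, d2$images)
  d3 <- build_dataset(cat1, 1, 1, 3, sim_config(), oc, seed = 22)
  expect_false(identical(d1$images, d3$images))
})

test_that("PNG round-trip preserves frames and manifest", {
  oc <- optical_config(frame_height_px = 16, frame_width_px = 16)
  ds <- build_dataset(pan_drug_catalog()[1:2], 1, 1, 2, sim_config(),
                      oc, seed = 2)
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  back <- read_dataset(root)
  expect_identical(back$images, ds$images)
  expect_equal(back$meta$drug, ds$meta$drug)
  expect_equal(back$meta$day, ds$meta$day)
})
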