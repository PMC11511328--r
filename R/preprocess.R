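#' Center-crop an image
#'
#' Extracts the centered `size x size` window; with a 1456 x 1088 frame
#' and the default size this reproduces the 224 x 224 crop used before
#' feature extraction (no interpolation, which would distort the speckle
#' statistics). The top-left corner sits at
#' `(floor((H - size)/2), floor((W - size)/2))` in 0-based coordinates.
#'
#' @param image 2-D matrix. @param size Crop side length in pixels.
#' @return The cropped `size x size` matrix.
#' @export
center_crop <- function(image, size = 224) {
  h <- nrow(image); w <- ncol(image)
  if (h < size || w < size) stop("image smaller than crop size")
  r0 <- floor((h - size) / 2)
  c0 <- floor((w - size) / 2)
  image[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), drop = FALSE]
}

#' Test whether a crop is statistically representative of the full frame
#'
#' Two-sample Kolmogorov-Smirnov test on the flattened gray levels of the
#' full frame and of the crop. A non-rejection supports treating the crop
#' as carrying the same first-order statistical information as the whole
#' frame (speckle is spatially stationary, so this should hold except
#' under vignetting or beam misalignment).
#'
#' Speckle pixels are spatially correlated over the grain size, which
#' violates the iid assumption of the KS test and inflates rejections;
#' `stride` subsamples every stride-th pixel in both axes so the tested
#' values are approximately independent. The default of 8 decorrelates
#' grains up to a few pixels wide; set `stride = 1` to use every pixel.
#'
#' @param full_image,cropped_image 2-D matrices.
#' @param alpha Significance level (default 0.01).
#' @param stride Pixel subsampling step (default 8).
#' @return List with `statistic`, `p_value`, `reject`.
#' @export
crop_representativeness_test <- function(full_image, cropped_image,
                                         alpha = 0.01, stride = 8L) {
  thin <- function(im) {
    if (identical(dim(im), NULL)) return(as.numeric(im))
    as.numeric(im[seq(1, nrow(im), by = stride),
                  seq(1, ncol(im), by = stride)])
  }
  x <- thin(full_image); y <- thin(cropped_image)
  if (length(full_image) == 0L || length(cropped_image) == 0L)
    stop("empty image")
  # gray levels are heavily tied; the asymptotic KS p-value is used
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       reject = kt$p.value < alpha)
}

#' Stratified train/test split of a dataset
#'
#' Frame-level stratified random partition: each drug contributes train
#' frames in proportion `fraction`, with the overall train size equal to
#' `round(fraction * n)` (largest-remainder apportionment across drugs,
#' residual to the largest stratum). Note that frame-level splitting
#' places frames of the same video on both sides; a video-level grouped
#' split is available via `unit = "video"` and avoids that leakage.
#'
#' @param ds A `speckle_dataset`. @param fraction Train fraction.
#' @param seed Integer seed. @param unit `"frame"` or `"video"`.
#' @return List of class `split_dataset` with `train`, `test`,
#'   `train_idx`, `test_idx`, `fraction`, `seed`.
#' @export
split_train_test <- function(ds, fraction = 0.8, seed = 1L,
                             unit = c("frame", "video")) {
  unit <- match.arg(unit)
  n <- nrow(ds$meta)
  if (n == 0L) stop("empty dataset")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  m <- ds$meta
  group <- if (unit == "frame") seq_len(n) else
    as.integer(factor(paste(m$drug, m$sample_id, m$video_id)))
  drugs <- unique(m$drug)
  # per-drug targets by largest remainder, constrained to round(f * n) units
  gtab <- unique(data.frame(group = group, drug = m$drug,
                            stringsAsFactors = FALSE))
  n_units <- nrow(gtab)
  total_target <- round(fraction * n_units)
  per <- table(factor(gtab$drug, levels = drugs))
  raw <- fraction * as.numeric(per)
  base <- floor(raw)
  resid <- total_target - sum(base)
  if (resid > 0) {
    ord <- order(raw - base, as.numeric(per), decreasing = TRUE)
    base[ord[seq_len(resid)]] <- base[ord[seq_len(resid)]] + 1
  } else if (resid < 0) {
    ord <- order(raw - base, as.numeric(per), decreasing = FALSE)
    base[ord[seq_len(-resid)]] <- base[ord[seq_len(-resid)]] - 1
  }
  train_units <- integer(0)
  rs <- withr::with_seed(seed, {
    for (k in seq_along(drugs)) {
      g <- gtab$group[gtab$drug == drugs[k]]
      train_units <- c(train_units, sample(g, base[k]))
    }
    train_units
  })
  train_idx <- which(group %in% rs)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train = subset_dataset(ds, train_idx),
                 test = subset_dataset(ds, test_idx),
                 train_idx = train_idx, test_idx = test_idx,
                 fraction = fraction, seed = seed, unit = unit),
            class = "split_dataset")
}

#' Fit the per-drug intensity normalizer
#'
#' Estimates, from training frames only, the pooled pixel mean and
#' standard deviation of each drug. Applying the model z-scores an image
#' with its drug's statistics and then min-max rescales it to
#' \[0, 255\] per image, which removes session-to-session brightness
#' drifts while preserving texture.
#'
#' @param train A `speckle_dataset` of training frames.
#' @return A `normalization_model`: per-drug `mean` and `sd`.
#' @export
fit_normalizer <- function(train) {
  drugs <- unique(train$meta$drug)
  stats_by <- lapply(drugs, function(d) {
    px <- unlist(lapply(train$images[train$meta$drug == d], as.numeric))
    c(mean = mean(px), sd = stats::sd(px))
  })
  mu <- vapply(stats_by, `[[`, numeric(1), "mean")
  sd <- vapply(stats_by, `[[`, numeric(1), "sd")
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("degenerate (zero-variance) training pixels for some drug")
  structure(list(drugs = drugs, mean = stats::setNames(mu, drugs),
                 sd = stats::setNames(sd, drugs)),
            class = "normalization_model")
}

#' Apply the per-drug normalizer to one image
#'
#' @param model A `normalization_model`. @param image 2-D matrix.
#' @param drug Drug label (must be known to the model).
#' @return Double matrix with values in \[0, 255\]; a constant input maps
#'   to all zeros.
#' @export
apply_normalizer <- function(model, image, drug) {
  if (!drug %in% model$drugs) stop("unknown drug label: ", drug)
  z <- (image - model$mean[[drug]]) / model$sd[[drug]]
  rng <- range(z)
  if (rng[2] == rng[1]) return(matrix(0, nrow(image), ncol(image)))
  (z - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Crop and normalize every frame of a split dataset
#'
#' Convenience wrapper: center-crops all frames, fits the normalizer on
#' the training crops, and applies it to both sides. Output pixel values
#' are rounded back to the integer 0..255 range expected by the texture
#' descriptors.
#'
#' @param split A `split_dataset`. @param crop_size Crop side length.
#' @return List `train`, `test` (datasets of normalized crops) and
#'   `normalizer`.
#' @export
preprocess_split <- function(split, crop_size = 224) {
  crop_all <- function(ds) {
    ds$images <- lapply(ds$images, center_crop, size = crop_size)
    ds
  }
  tr <- crop_all(split$train); te <- crop_all(split$test)
  norm <- fit_normalizer(tr)
  norm_all <- function(ds) {
    ds$images <- lapply(seq_along(ds$images), function(i) {
      img <- apply_normalizer(norm, ds$images[[i]], ds$meta$drug[i])
      img <- round(img)
      storage.mode(img) <- "integer"
      img
    })
    ds
  }
  list(train = norm_all(tr), test = norm_all(te), normalizer = norm)
}
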