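#' Simulator configuration
#'
#' Parameters of the synthetic dynamic-speckle generator. The simulator
#' draws a circular complex Gaussian field, low-pass filters it to set
#' the speckle grain size, and evolves it over time by partial field
#' replacement, which emulates the Brownian decorrelation of scatterers
#' in suspension. A per-session multiplicative gain emulates minor
#' fluctuations in laser power and acquisition conditions between
#' measurement sessions.
#'
#' @param grain_size_px Speckle correlation length rho in pixels (>= 1).
#' @param temporal_mixing Per-frame field replacement fraction epsilon in
#'   \[0, 1\]; successive intensity frames correlate as ~ (1 - epsilon).
#' @param session_gain_sd SD of the log-normal per-session gain jitter.
#' @param mean_intensity_scale Mean gray level at unit brightness (B = 1);
#'   in (0, 255\].
#' @return A `sim_config` object.
#' @export
sim_config <- function(grain_size_px = 3,
                       temporal_mixing = 0.3,
                       session_gain_sd = 0.02,
                       mean_intensity_scale = 120) {
  if (grain_size_px < 1) stop("grain_size_px must be >= 1")
  if (temporal_mixing < 0 || temporal_mixing > 1)
    stop("temporal_mixing must be in [0, 1]")
  if (session_gain_sd < 0) stop("session_gain_sd must be >= 0")
  if (mean_intensity_scale <= 0 || mean_intensity_scale > 255)
    stop("mean_intensity_scale must be in (0, 255]")
  structure(list(grain_size_px = grain_size_px,
                 temporal_mixing = temporal_mixing,
                 session_gain_sd = session_gain_sd,
                 mean_intensity_scale = mean_intensity_scale),
            class = "sim_config")
}

# Deterministic sub-seed derivation: a small LCG-style hash over the
# master seed and stage/frame indices, kept below 2^31 so any frame is
# reproducible in isolation without replaying the whole stream.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed %% m)
  for (ix in c(...)) s <- (s * 69069 + as.double(ix) + 1) %% m
  as.integer(s)
}

# Gaussian low-pass transfer function on the FFT grid of an h x w frame.
speckle_transfer <- function(h, w, rho) {
  fu <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[seq_len(h)] / h
  fv <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[seq_len(w)] / w
  exp(-2 * pi^2 * rho^2 * outer(fu^2, fv^2, `+`))
}

# One unit-variance filtered circular Gaussian field (complex h x w).
# <|A|^2> = 1 by construction.
speckle_white_field <- function(h, w, transfer) {
  wf <- matrix(complex(real = stats::rnorm(h * w),
                       imaginary = stats::rnorm(h * w)), h, w)
  a <- stats::fft(stats::fft(wf) * transfer, inverse = TRUE) / (h * w)
  a / sqrt(2 * mean(transfer^2))
}

intensity_to_frame <- function(intensity, quantize) {
  if (!quantize) return(intensity)
  img <- round(pmin(pmax(intensity, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Simulate one speckle frame
#'
#' Draws a complex circular-Gaussian white field, low-pass filters it
#' with a Gaussian kernel of width `grain_size_px`, takes the intensity
#' |A|^2 (exponentially distributed, unit contrast: fully developed
#' speckle), rescales it so the ensemble-mean gray level equals
#' `B * mean_intensity_scale * gain`, then clips to \[0, 255\] and
#' quantizes to 8 bits.
#'
#' @param B Brightness factor in \[0, 1\], see [brightness_factor()].
#' @param sim A [sim_config()].
#' @param cfg An [optical_config()] (frame dimensions).
#' @param seed Optional integer seed; when given the frame is drawn from
#'   its own reproducible stream.
#' @param gain Multiplicative session gain (default 1).
#' @param quantize If `FALSE`, return the continuous pre-quantization
#'   intensity (used for distributional checks).
#' @return Integer (or double, if `quantize = FALSE`) matrix of size
#'   `frame_height_px x frame_width_px`.
#' @export
simulate_frame <- function(B, sim = sim_config(), cfg = optical_config(),
                           seed = NULL, gain = 1, quantize = TRUE) {
  if (!is.numeric(B) || B < 0 || B > 1) stop("B must be in [0, 1]")
  h <- cfg$frame_height_px; w <- cfg$frame_width_px
  draw <- function() {
    a <- speckle_white_field(h, w, speckle_transfer(h, w, sim$grain_size_px))
    intensity_to_frame(Mod(a)^2 * (B * gain * sim$mean_intensity_scale),
                       quantize)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a dynamic speckle video
#'
#' Evolves the underlying complex field as
#' `A[t+1] = sqrt(1 - eps) * A[t] + sqrt(eps) * N[t]` with `N[t]` fresh
#' filtered white noise, so the expected Pearson correlation of
#' successive intensity frames is approximately `1 - eps`.
#'
#' @inheritParams simulate_frame
#' @param n_frames Number of frames (>= 1).
#' @return A list of class `frame_stack` with elements `frames` (list of
#'   matrices) and the generating parameters.
#' @export
simulate_video <- function(B, n_frames, sim = sim_config(),
                           cfg = optical_config(), seed = NULL, gain = 1,
                           quantize = TRUE) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  h <- cfg$frame_height_px; w <- cfg$frame_width_px
  eps <- sim$temporal_mixing
  run <- function() {
    tr <- speckle_transfer(h, w, sim$grain_size_px)
    a <- speckle_white_field(h, w, tr)
    frames <- vector("list", n_frames)
    scale <- B * gain * sim$mean_intensity_scale
    frames[[1L]] <- intensity_to_frame(Mod(a)^2 * scale, quantize)
    for (t in seq_len(n_frames - 1L)) {
      a <- sqrt(1 - eps) * a + sqrt(eps) * speckle_white_field(h, w, tr)
      frames[[t + 1L]] <- intensity_to_frame(Mod(a)^2 * scale, quantize)
    }
    frames
  }
  frames <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(frames = frames, B = B, gain = gain, sim = sim, cfg = cfg),
            class = "frame_stack")
}

#' Build a full labeled synthetic dataset
#'
#' Emits the acquisition layout used throughout the analysis: for each
#' drug, `samples_per_drug` physical samples (the first half tagged day
#' 0, the second half day 2), `videos_per_sample` videos of
#' `frames_per_video` frames each. Each (drug, sample) measurement
#' session draws one multiplicative log-normal gain applied to all its
#' frames. With the defaults (6 drugs x 4 x 3 x 100) the dataset holds
#' 7200 frames, 1200 per drug.
#'
#' @param catalog List of [drug_spec()].
#' @param samples_per_drug,videos_per_sample,frames_per_video Layout counts.
#' @param sim A [sim_config()]. @param cfg An [optical_config()].
#' @param seed Master seed; every session and video derives its own
#'   sub-seed from it.
#' @return A `speckle_dataset`: list with `images` (list of matrices) and
#'   `meta` (data.frame: drug, sample_id, video_id, frame_index, day).
#' @export
build_dataset <- function(catalog, samples_per_drug = 4,
                          videos_per_sample = 3, frames_per_video = 100,
                          sim = sim_config(), cfg = optical_config(),
                          seed = 1L) {
  stopifnot(length(catalog) >= 1, samples_per_drug >= 1,
            videos_per_sample >= 1, frames_per_video >= 1)
  images <- list()
  meta <- list()
  for (di in seq_along(catalog)) {
    drug <- catalog[[di]]
    B <- brightness_factor(drug, catalog)
    for (si in seq_len(samples_per_drug)) {
      day <- if (si <= ceiling(samples_per_drug / 2)) 0L else 2L
      gain <- withr::with_seed(
        derive_seed(seed, 1L, di, si),
        exp(stats::rnorm(1, 0, sim$session_gain_sd)))
      for (vi in seq_len(videos_per_sample)) {
        vs <- derive_seed(seed, 2L, di, si, vi)
        stack <- simulate_video(B, frames_per_video, sim, cfg,
                                seed = vs, gain = gain)
        images <- c(images, stack$frames)
        meta[[length(meta) + 1L]] <- data.frame(
          drug = drug$name, sample_id = si, video_id = vi,
          frame_index = seq_len(frames_per_video), day = day,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(images = images, meta = do.call(rbind, meta), seed = seed,
                 sim = sim, cfg = cfg),
            class = "speckle_dataset")
}

#' @export
length.speckle_dataset <- function(x) length(x$images)

#' @export
print.speckle_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("speckle_dataset: %d frames, %d drugs, %dx%d px\n",
              nrow(m), length(unique(m$drug)),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  print(table(m$drug))
  invisible(x)
}

#' Subset a dataset by frame index
#' @param ds A `speckle_dataset`. @param idx Integer or logical index.
#' @return A `speckle_dataset` with the selected frames.
#' @export
subset_dataset <- function(ds, idx) {
  out <- ds
  out$images <- ds$images[idx]
  out$meta <- ds$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Write a dataset to disk as PNG frames plus a CSV manifest
#'
#' Frames go to `<root>/<drug>/s<sample>/v<video>/frame_####.png` as 8-bit
#' grayscale PNG; the manifest (`manifest.csv`) records path, drug,
#' sample, video, frame and day; simulator settings go to
#' `settings.json`.
#'
#' @param ds A `speckle_dataset`. @param root Output directory.
#' @return Invisibly, the manifest data.frame.
#' @export
write_dataset <- function(ds, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  m <- ds$meta
  safe <- gsub("[^A-Za-z0-9_-]+", "_", m$drug)
  rel <- file.path(safe, sprintf("s%d", m$sample_id),
                   sprintf("v%d", m$video_id),
                   sprintf("frame_%04d.png", m$frame_index))
  for (i in seq_along(ds$images)) {
    p <- file.path(root, rel[i])
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(ds$images[[i]] / 255, p)
  }
  manifest <- cbind(data.frame(path = rel, stringsAsFactors = FALSE), m)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(sim = unclass(ds$sim), cfg = unclass(ds$cfg),
                            seed = ds$seed),
                       file.path(root, "settings.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param root Directory holding `manifest.csv` and PNG frames.
#' @return A `speckle_dataset`.
#' @export
read_dataset <- function(root) {
  manifest <- utils::read.csv(file.path(root, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(root, p))
    img <- round(img * 255)
    storage.mode(img) <- "integer"
    img
  })
  meta <- manifest[, c("drug", "sample_id", "video_id", "frame_index", "day")]
  structure(list(images = images, meta = meta), class = "speckle_dataset")
}
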