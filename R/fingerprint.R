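# Per-cycle spectral fingerprints and classifier images.
#
# The CWT spectrum is cut at the cardiac-cycle boundaries, each cycle is
# resized in time to a fixed 16,000-column grid (1 s at 16 kHz) by
# nearest-neighbor interpolation, cycles are averaged pixel by pixel into a
# per-subject fingerprint, and each cycle is rendered as a 134 x 134 x 3
# colormapped image in [0, 1] for the classifier.

#' Cut a CWT spectrum at cardiac-cycle boundaries
#'
#' @param spec a `carotid_cwt`.
#' @param cycles data.frame with `start_sample`, `end_sample` expressed at
#'   `cycles_fs` (the audio rate the boundaries were derived at).
#' @param cycles_fs sample rate of the boundary indices; defaults to the
#'   spectrum's own rate.
#' @return list of magnitude matrices, one per cycle, order preserved.
#' @export
segment_spectrum <- function(spec, cycles, cycles_fs = NULL) {
  stopifnot(inherits(spec, "carotid_cwt"))
  n <- ncol(spec$magnitude)
  ratio <- (cycles_fs %||% spec$fs) / spec$fs
  lapply(seq_len(nrow(cycles)), function(i) {
    c0 <- floor((cycles$start_sample[i] - 1) / ratio) + 1
    c1 <- ceiling(cycles$end_sample[i] / ratio)
    if (c0 < 1 || c1 > n || c1 < c0)
      stop("cycle boundary out of spectrum range")
    spec$magnitude[, c0:c1, drop = FALSE]
  })
}

# Nearest-neighbor index map: output index j picks input index
# floor((j - 0.5) * w_in / w_out) + 1.
nn_index <- function(w_in, w_out) {
  pmin(w_in, floor((seq_len(w_out) - 0.5) * w_in / w_out) + 1L)
}

#' Resize a cycle spectrum in time by nearest-neighbor interpolation
#'
#' @param mat magnitude matrix (freqs x time).
#' @param target_len output column count; 16,000 columns represent one
#'   second at 16 kHz.
#' @return matrix with `target_len` columns; the frequency axis untouched.
#' @export
resize_cycle <- function(mat, target_len = 16000) {
  if (!is.matrix(mat) || ncol(mat) == 0) stop("zero-width cycle")
  mat[, nn_index(ncol(mat), target_len), drop = FALSE]
}

#' Pixel-wise average of cycle spectra
#'
#' @param cycles list of equally-shaped matrices (resized cycle spectra).
#' @return a `carotid_fingerprint` matrix with attribute `n_cycles`.
#' @export
average_spectra <- function(cycles) {
  if (!length(cycles)) stop("empty cycle list")
  dims <- dim(cycles[[1]])
  if (!all(vapply(cycles, function(m) identical(dim(m), dims), TRUE)))
    stop("cycle shape mismatch")
  fp <- Reduce(`+`, cycles) / length(cycles)
  attr(fp, "n_cycles") <- length(cycles)
  class(fp) <- c("carotid_fingerprint", class(fp))
  fp
}

#' Fixed 256-entry RGB colormap
#'
#' A procedurally generated jet-style lookup table, fixed so that rendered
#' images are bit-stable across platforms.
#'
#' @return 256 x 3 matrix with values in \[0, 1\].
#' @export
default_colormap <- function() {
  v <- (0:255) / 255
  clamp <- function(z) pmax(0, pmin(1, z))
  cbind(r = clamp(1.5 - abs(4 * v - 3)),
        g = clamp(1.5 - abs(4 * v - 2)),
        b = clamp(1.5 - abs(4 * v - 1)))
}

#' Render a cycle spectrum as a fixed-size RGB image
#'
#' Magnitude is log-compressed as `log(1 + m / (1e-3 * max(m)))` (making the
#' rendering invariant to overall amplitude), min-max normalized per image,
#' nearest-neighbor resized to `size x size`, and mapped through a fixed
#' 256-entry colormap.  All channel values lie in \[0, 1\].
#'
#' @param mat cycle magnitude matrix (freqs x time).
#' @param size output image side length.
#' @param lut 256 x 3 colormap.
#' @return array `size x size x 3` in \[0, 1\].
#' @export
render_cycle_image <- function(mat, size = 134, lut = default_colormap()) {
  if (!is.matrix(mat) || ncol(mat) == 0) stop("zero-width cycle")
  mx <- max(mat)
  if (mx > 0) {
    v <- log1p(mat / (1e-3 * mx))
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  } else {
    v <- mat
  }
  v <- v[nn_index(nrow(v), size), nn_index(ncol(v), size), drop = FALSE]
  idx <- matrix(as.integer(round(v * 255)) + 1L, nrow(v), ncol(v))
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- lut[idx, ch]
  img
}

# Flatten a list of H x W x 3 images into the channel-fastest D x n matrix
# consumed by the CNN backend (D = 3 * H * W).
images_to_matrix <- function(images) {
  d <- dim(images[[1]])
  D <- prod(d)
  out <- matrix(0, nrow = D, ncol = length(images))
  for (i in seq_along(images))
    out[, i] <- as.numeric(aperm(images[[i]], c(3, 1, 2)))
  attr(out, "img_dim") <- d
  out
}

#' Per-recording spectral fingerprint
#'
#' Convenience wrapper: cut, resize and average all cycles of one spectrum.
#'
#' @inheritParams segment_spectrum
#' @param target_len resized cycle length in columns.
#' @return a `carotid_fingerprint`.
#' @export
recording_fingerprint <- function(spec, cycles, cycles_fs = NULL,
                                  target_len = 16000) {
  segs <- segment_spectrum(spec, cycles, cycles_fs)
  average_spectra(lapply(segs, resize_cycle, target_len = target_len))
}
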