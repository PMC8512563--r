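# Continuous wavelet transform with generalized Morse wavelets.
#
# The Morse family is parameterized by a shape exponent gamma and a decay
# exponent beta; gamma = 3 gives the symmetric member and the time-bandwidth
# product is gamma * beta.  The transform is computed in the frequency
# domain: the FFT of the (symmetrically padded) signal is multiplied by the
# sampled analytic Morse filter at each scale and inverted.  Scales follow a
# geometric grid with a fixed number of voices per octave, reported as
# pseudo-frequencies via the wavelet's peak frequency.

#' Morse wavelet parameters
#'
#' @param gamma shape exponent; 3 is the perfectly symmetric member.
#' @param beta decay exponent; with `gamma = 3`, `beta = 20` gives a
#'   time-bandwidth product of 60.
#' @return a `morse_params` object.
#' @export
morse_params <- function(gamma = 3, beta = 20) {
  if (!(gamma > 0) || !(beta > (gamma - 1) / 2))
    stop("invalid Morse parameters: need gamma > 0 and beta > (gamma-1)/2")
  structure(list(gamma = gamma, beta = beta,
                 time_bandwidth = gamma * beta),
            class = "morse_params")
}

#' Peak (radian) frequency of a Morse wavelet
#'
#' The mode of the Morse frequency-domain window, `(beta/gamma)^(1/gamma)`,
#' used to map scales to pseudo-frequencies.
#'
#' @param p a `morse_params` object.
#' @return peak frequency in radians.
#' @export
morse_peak_frequency <- function(p) {
  stopifnot(inherits(p, "morse_params"))
  (p$beta / p$gamma)^(1 / p$gamma)
}

# Morse frequency-domain window evaluated at radian frequencies w >= 0,
# normalized to peak value 2 (so a unit-amplitude real tone yields ridge
# magnitude ~1 in the analytic transform).
morse_window <- function(w, p) {
  wp <- morse_peak_frequency(p)
  out <- numeric(length(w))
  pos <- w > 0
  u <- w[pos] / wp
  out[pos] <- 2 * exp(p$beta * log(u) - (p$beta / p$gamma) * (u^p$gamma - 1))
  out
}

#' Continuous wavelet transform of a recording
#'
#' @param x a `carotid_recording` or numeric vector.
#' @param fs sampling frequency (taken from `x` if it is a recording).
#' @param params `morse_params`.
#' @param voices_per_octave scale resolution of the geometric frequency grid.
#' @param f_min,f_max analysis band in Hz; `f_max` must not exceed `fs/2`.
#'   The default band \[1, 200\] Hz covers the spectral structure relevant to
#'   carotid-sound fingerprints; pass `f_max = fs/2` for full-band analysis.
#' @param pad_factor symmetric padding length in units of the slowest
#'   wavelet's duration (`pad_factor / f_min` seconds each side), capped at
#'   the signal length.
#' @return a `carotid_cwt`: list with `magnitude` (n_freqs x n_samples,
#'   non-negative), `freqs` (Hz, strictly decreasing, log-spaced), `fs`,
#'   `params`.
#' @export
compute_cwt <- function(x, fs = NULL, params = morse_params(),
                        voices_per_octave = 10, f_min = 1, f_max = 200,
                        pad_factor = 3.7) {
  if (inherits(x, "carotid_recording")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs required for a plain numeric signal")
  n <- length(x)
  if (n == 0) stop("empty signal")
  if (f_min >= f_max) stop("f_min must be < f_max")
  if (f_max > fs / 2) stop("f_max must not exceed fs/2")
  nv <- floor(voices_per_octave * log2(f_max / f_min))
  freqs <- f_max * 2^(-(0:nv) / voices_per_octave)
  pad <- min(n, ceiling(pad_factor * fs / f_min))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  m <- nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(m - length(xp)))
  X <- fft(xp)
  half <- 0:(m %/% 2)
  w_grid <- 2 * pi * half / m               # radians per sample
  wp <- morse_peak_frequency(params)
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  Y <- complex(length.out = m)
  for (i in seq_along(freqs)) {
    s <- wp * fs / (2 * pi * freqs[i])      # scale in samples
    psi <- morse_window(s * w_grid, params)
    Y[] <- 0
    Y[half + 1L] <- X[half + 1L] * psi
    row <- fft(Y, inverse = TRUE)[pad + seq_len(n)] / m
    mag[i, ] <- Mod(row)
  }
  structure(list(magnitude = mag, freqs = freqs, fs = fs, params = params,
                 voices_per_octave = voices_per_octave),
            class = "carotid_cwt")
}

#' @export
print.carotid_cwt <- function(x, ...) {
  cat(sprintf(
    "<carotid_cwt: %d freqs [%.2f-%.2f Hz] x %d samples @ %g Hz, gamma=%g beta=%g>\n",
    length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$magnitude), x$fs,
    x$params$gamma, x$params$beta))
  invisible(x)
}
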