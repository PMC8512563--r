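# Quality screening: automated surrogate for the visual accept/reject step.
# A recording passes when enough S1 and S2 transients are recognizable
# relative to the number of cardiac cycles expected from the estimated
# heart rate.

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  i0 <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  i1 <- pmin(n, seq_len(n) + (w %/% 2L))
  (cs[i1 + 1L] - cs[i0 + 1L]) / (i1 - i0)
}

block_mean <- function(x, b) {
  n <- floor(length(x) / b)
  colMeans(matrix(x[seq_len(n * b)], nrow = b))
}

# Heart rate (bpm) from the autocorrelation of a slow envelope sampled at
# `rate` Hz; peak lag searched in [0.43, 1.5] s (40-140 bpm), refined by
# parabolic interpolation.  Falls back to `prior` bpm with a warning when
# no periodicity is found.
hr_from_envelope <- function(env, rate, prior = 70, min_corr = 0.15) {
  lag_max <- min(length(env) - 2L, ceiling(1.5 * rate))
  a <- stats::acf(env, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lo <- max(2L, round(0.43 * rate))
  if (lo + 2 > lag_max) {
    warning("envelope too short for heart-rate search; using prior")
    return(prior)
  }
  lags <- lo:lag_max
  k <- lags[which.max(a[lags + 1L])]
  if (a[k + 1L] < min_corr) {
    warning("no periodicity in envelope; falling back to prior heart rate")
    return(prior)
  }
  # parabolic refinement around the integer-lag peak
  y1 <- a[k]; y2 <- a[k + 1L]; y3 <- a[min(length(a), k + 2L)]
  denom <- (y1 - 2 * y2 + y3)
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  60 / ((k + delta) / rate)
}

#' Load a mono WAV recording and peak-normalize it
#'
#' @param path path to a mono 16-bit PCM WAV file.
#' @param user_id,device_id,side optional provenance labels.
#' @return a `carotid_recording` with `max(abs(samples)) == 1`.
#' @export
load_recording <- function(path, user_id = NA, device_id = NA, side = NA) {
  w <- read_wav(path)
  x <- as.numeric(w$samples)
  m <- max(abs(x))
  if (m == 0) stop("degenerate input: all-zero signal in ", path)
  structure(list(samples = x / m, fs = w$fs,
                 duration = length(x) / w$fs,
                 user_id = user_id, device_id = device_id, side = side,
                 truth_states = NULL),
            class = "carotid_recording")
}

# Smoothed 25-400 Hz envelope at ~1 kHz, used by both event detection and
# heart-rate estimation.
quality_envelope <- function(rec, smooth_s = 0.05) {
  fs <- rec$fs
  bf <- signal::butter(4, c(25, 400) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, rec$samples)
  dec <- max(1L, floor(fs / 1000))
  xd <- xb[seq(1, length(xb), by = dec)]
  fs1 <- fs / dec
  env <- Mod(analytic_signal(xd))
  list(env = moving_average(env, round(smooth_s * fs1)), fs = fs1, dec = dec)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Greedy peak picking: highest peaks first, enforcing a minimum distance.
pick_peaks <- function(env, min_dist) {
  cand <- local_maxima(env)
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= min_dist)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Detect S1 and S2 event candidates
#'
#' Peak picking on a smoothed 25-400 Hz envelope.  Beat-level peaks (one per
#' expected cardiac cycle, the larger transients) are taken as S1 candidates;
#' within each beat the largest later, smaller peak in the systolic window is
#' the S2 candidate, accepted only when it rises above the flow-noise floor.
#'
#' @param rec a `carotid_recording`.
#' @param smooth_s envelope smoothing window, seconds.
#' @param min_dist_s minimum inter-peak distance, seconds.
#' @param s2_floor S2 acceptance threshold as a multiple of the median
#'   envelope (the noise floor).
#' @param s2_rel S2 acceptance threshold relative to the typical (median)
#'   S1 peak height.
#' @return list with `s1_peaks`, `s2_peaks` (sample indices at `rec$fs`),
#'   and `heart_rate` (bpm).
#' @export
detect_event_candidates <- function(rec, smooth_s = 0.05, min_dist_s = 0.2,
                                    s2_floor = 1.5, s2_rel = 0.25) {
  if (rec$duration < 2) stop("recording shorter than 2 s")
  if (max(abs(rec$samples)) == 0) stop("degenerate input: all-zero signal")
  qe <- quality_envelope(rec, smooth_s)
  env <- qe$env; fs1 <- qe$fs
  hr <- suppressWarnings(hr_from_envelope(block_mean(env, round(fs1 / 50)), 50))
  period <- 60 / hr * fs1
  peaks <- pick_peaks(env, round(min_dist_s * fs1))
  if (!length(peaks))
    return(list(s1_peaks = integer(0), s2_peaks = integer(0), heart_rate = hr))
  # beat-level (S1) peaks: one per period, then drop stragglers far below
  # the typical beat peak
  s1 <- pick_peaks(env, round(0.75 * period))
  n_beats <- max(1, floor(rec$duration * hr / 60))
  top <- sort(env[s1], decreasing = TRUE)[seq_len(min(n_beats, length(s1)))]
  s1 <- s1[env[s1] >= 0.5 * median(top)]
  # a beat peak can be the S2 when amplitude jitter makes it the taller
  # transient; if a comparable peak sits 0.15-0.45 periods earlier (the
  # S1-S2 spacing), take that earlier peak as the S1
  s1 <- sort(unique(vapply(s1, function(b) {
    cand <- peaks[peaks >= b - round(0.45 * period) &
                  peaks <= b - round(0.15 * period)]
    cand <- cand[env[cand] >= 0.6 * env[b]]
    if (length(cand)) cand[which.max(env[cand])] else b
  }, 0)))
  noise_floor <- median(env)
  s2_min <- max(s2_floor * noise_floor, s2_rel * median(env[s1]))
  s2 <- integer(0)
  # search the systolic window after each S1, sized by the heart period so
  # a single missed or spurious S1 does not corrupt neighboring beats
  for (i in seq_along(s1)) {
    nxt <- if (i < length(s1)) s1[i + 1L] else length(env)
    w0 <- s1[i] + round(0.18 * period)
    w1 <- min(s1[i] + round(0.60 * period), nxt - round(0.15 * period),
              length(env))
    if (w1 <= w0) next
    inwin <- peaks[peaks > w0 & peaks <= w1]
    if (!length(inwin)) next
    p <- inwin[which.max(env[inwin])]
    if (env[p] >= s2_min && env[p] <= 1.2 * env[s1[i]])
      s2 <- c(s2, p)
  }
  list(s1_peaks = (s1 - 1L) * qe$dec + 1L,
       s2_peaks = (s2 - 1L) * qe$dec + 1L,
       heart_rate = hr)
}

#' Assess the signal quality of a recording
#'
#' A recording passes when at least `threshold` of the expected number of
#' cardiac cycles (from the estimated heart rate) have both a recognizable
#' S1 and a recognizable S2 candidate.
#'
#' @param rec a `carotid_recording`.
#' @param threshold required detected fraction of expected cycles.
#' @param ... passed to [detect_event_candidates()].
#' @return a `quality_report` list: `n_expected_cycles`, `n_s1_detected`,
#'   `n_s2_detected`, `heart_rate`, `pass`.
#' @export
assess_quality <- function(rec, threshold = 0.7, ...) {
  ev <- detect_event_candidates(rec, ...)
  n_expected <- max(1L, floor(rec$duration * ev$heart_rate / 60))
  rep <- list(n_expected_cycles = n_expected,
              n_s1_detected = length(ev$s1_peaks),
              n_s2_detected = length(ev$s2_peaks),
              heart_rate = ev$heart_rate,
              pass = length(ev$s1_peaks) >= threshold * n_expected &&
                     length(ev$s2_peaks) >= threshold * n_expected)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report: %d expected, %d S1, %d S2 -> %s>\n",
              x$n_expected_cycles, x$n_s1_detected, x$n_s2_detected,
              if (x$pass) "PASS" else "REJECT"))
  invisible(x)
}
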