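# Synthetic carotid-sound generator.
#
# Each simulated subject is a `carotid_profile`: a heart-rate distribution,
# S1/S2 tone-burst morphologies, and a subject-specific "murmur" band -- the
# band-limited flow-noise envelope that carries most of the between-subject
# spectral identity (real carotid spectra concentrate their discriminative
# energy roughly between 4 and 100 Hz).  Recordings are sums of
# Gaussian-windowed multi-tone S1/S2 bursts, bandpass-filtered flow noise
# with a systolic gain boost, and broadband sensor noise, normalized to
# peak amplitude 1.  Ground-truth cardiac states are returned alongside.

#' Create synthetic subject profiles
#'
#' Murmur-band centers are placed on a log-frequency grid inside
#' \[`f_lo`, `f_hi`\] Hz.  `separation` requests a minimum pairwise spacing of
#' that many octaves between band centers; when `n_users` centers cannot fit
#' in the band at the requested spacing, the spacing is capped at the largest
#' feasible value (the band limits take precedence).
#'
#' @param n_users number of subjects (>= 2).
#' @param seed integer seed; profiles are a pure function of it.
#' @param separation requested spacing between murmur-band centers, in
#'   octaves, in \[0, 1\].
#' @param f_lo,f_hi frequency limits (Hz) that all murmur bands must respect.
#' @return list of `carotid_profile` objects.
#' @export
make_profiles <- function(n_users, seed = 1, separation = 0.8,
                          f_lo = 4, f_hi = 100) {
  if (!is.numeric(n_users) || n_users < 2)
    stop("n_users must be >= 2")
  if (separation < 0 || separation > 1)
    stop("separation must be in [0, 1]")
  n_users <- as.integer(n_users)
  bw <- 0.8  # murmur band width, octaves
  lo_c <- f_lo * 2^(bw / 2)
  hi_c <- f_hi * 2^(-bw / 2)
  span <- log2(hi_c / lo_c)
  step <- min(separation, span / (n_users - 1))
  start <- log2(lo_c) + (span - step * (n_users - 1)) / 2
  centers <- 2^(start + step * (0:(n_users - 1)))
  with_seed(seed, {
    lapply(seq_len(n_users), function(i) {
      s1f <- runif(1, 28, 40)
      s2f <- runif(1, 50, 75)
      p <- list(
        user_id = sprintf("U%d", i),
        hr_mean = runif(1, 70, 95),
        hr_sd = runif(1, 1.5, 3.5),
        s1_freqs = c(s1f, 1.6 * s1f),
        s1_amps = c(1, 0.6),
        s2_freqs = c(s2f, 1.5 * s2f),
        s2_amps = c(0.7, 0.4),
        s1_dur = runif(1, 0.09, 0.13),
        s2_dur = runif(1, 0.07, 0.10),
        murmur_band = c(centers[i] * 2^(-bw / 2), centers[i] * 2^(bw / 2)),
        murmur_gain = runif(1, 0.09, 0.15),
        side_asymmetry = runif(1, 0.88, 0.98)
      )
      stopifnot(p$hr_mean >= 40, p$hr_mean <= 140,
                all(c(p$s1_freqs, p$s2_freqs, p$murmur_band) > 0),
                all(c(p$s1_freqs, p$s2_freqs, p$murmur_band) < 8000),
                p$s1_dur > 0.02, p$s1_dur < 0.25,
                p$s2_dur > 0.02, p$s2_dur < 0.25)
      class(p) <- "carotid_profile"
      p
    })
  })
}

#' @export
print.carotid_profile <- function(x, ...) {
  cat(sprintf("<carotid_profile %s: HR %.1f bpm, murmur band %.1f-%.1f Hz>\n",
              x$user_id, x$hr_mean, x$murmur_band[1], x$murmur_band[2]))
  invisible(x)
}

# Gaussian-windowed multi-tone burst added in place.
add_burst <- function(x, fs, t_start, dur, freqs, amps, phases, gain) {
  n <- length(x)
  i0 <- max(1L, floor(t_start * fs) + 1L)
  i1 <- min(n, ceiling((t_start + dur) * fs))
  if (i1 < i0) return(x)
  tt <- ((i0:i1) - 1) / fs - (t_start + dur / 2)
  env <- exp(-0.5 * (tt / (dur / 6))^2)
  tone <- numeric(length(tt))
  for (k in seq_along(freqs))
    tone <- tone + amps[k] * sin(2 * pi * freqs[k] * tt + phases[k])
  x[i0:i1] <- x[i0:i1] + gain * env * tone
  x
}

#' Simulate one carotid sound recording
#'
#' @param profile a `carotid_profile`.
#' @param duration recording length in seconds (must fit >= 2 cardiac
#'   cycles at the profile's mean heart rate).
#' @param fs sampling frequency, Hz.
#' @param seed integer seed.
#' @param low_quality if `TRUE`, S2 bursts are attenuated below the flow
#'   noise floor, emulating recordings whose S2 events are not recognizable.
#' @param side `"L"` or `"R"`; the right side applies the profile's
#'   `side_asymmetry` gain to the murmur component.
#' @param device_gain_db per-device gain perturbation in dB.
#' @param device_lp_hz optional first-order low-pass cutoff (Hz) emulating a
#'   device's gentle high-frequency roll-off.
#' @param user_id,device_id labels recorded in the result.
#' @return a `carotid_recording`: list with `samples` (peak-normalized to 1),
#'   `fs`, `duration`, labels, and `truth_states`, a data.frame of
#'   `(start_sample, end_sample, state)` ground-truth spans.
#' @export
simulate_recording <- function(profile, duration = 11, fs = 16000, seed = 1,
                               low_quality = FALSE, side = "L",
                               device_gain_db = 0, device_lp_hz = NULL,
                               user_id = profile$user_id, device_id = "D1") {
  if (!inherits(profile, "carotid_profile")) stop("profile required")
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(fs) || fs <= 0)
    stop("duration and fs must be positive")
  if (duration <= 2 / (profile$hr_mean / 60))
    stop("duration too short for two cardiac cycles")
  side <- match.arg(side, c("L", "R"))
  n <- round(duration * fs)
  with_seed(seed, {
    rr_mean <- 60 / profile$hr_mean
    rr_sd <- rr_mean * profile$hr_sd / profile$hr_mean
    # cycle onset times; recording starts at a random phase of the cycle
    t0 <- -runif(1, 0, 0.9 * rr_mean)
    onsets <- t0
    while (tail(onsets, 1) < duration) {
      rr <- max(0.4, rnorm(1, rr_mean, rr_sd))
      onsets <- c(onsets, tail(onsets, 1) + rr)
    }
    x <- numeric(n)
    spans <- list()
    s2_gain <- if (low_quality) 0.05 else 1
    sys_ind <- numeric(n)
    for (ci in seq_len(length(onsets) - 1)) {
      c0 <- onsets[ci]
      rr <- onsets[ci + 1] - c0
      s1d <- profile$s1_dur
      s2d <- profile$s2_dur
      sysd <- max(0.12, 0.32 * rr - s1d)
      jit1 <- runif(1, 0.85, 1.15)
      jit2 <- runif(1, 0.85, 1.15)
      # beat-to-beat pitch variability of the heart-sound transients
      fjit1 <- runif(1, 0.85, 1.15)
      fjit2 <- runif(1, 0.85, 1.15)
      x <- add_burst(x, fs, c0, s1d, profile$s1_freqs * fjit1,
                     profile$s1_amps,
                     runif(length(profile$s1_freqs), 0, 2 * pi), jit1)
      x <- add_burst(x, fs, c0 + s1d + sysd, s2d, profile$s2_freqs * fjit2,
                     profile$s2_amps,
                     runif(length(profile$s2_freqs), 0, 2 * pi),
                     jit2 * s2_gain)
      # systolic murmur boost spans S1 onset to S2 end
      b0 <- max(1L, floor(c0 * fs) + 1L)
      b1 <- min(n, ceiling((c0 + s1d + sysd + s2d) * fs))
      if (b1 >= b0) sys_ind[b0:b1] <- 1
      spans[[length(spans) + 1L]] <- data.frame(
        t0 = c(c0, c0 + s1d, c0 + s1d + sysd, c0 + s1d + sysd + s2d),
        t1 = c(c0 + s1d, c0 + s1d + sysd, c0 + s1d + sysd + s2d, c0 + rr),
        state = c("S1", "systole", "S2", "diastole"))
    }
    # murmur: bandpass-filtered white noise plus a narrow resonant component
    # at the band center (users show peaked spectral signatures), with a
    # systolic gain boost
    band <- profile$murmur_band / (fs / 2)
    bf <- signal::butter(2, band, type = "pass")
    broad <- signal::filtfilt(bf, rnorm(n))
    fc <- sqrt(profile$murmur_band[1] * profile$murmur_band[2])
    r <- exp(-pi * max(0.8, 0.04 * fc) / fs)
    theta <- 2 * pi * fc / fs
    res <- signal::filter(signal::Arma(b = 1 - r,
                                       a = c(1, -2 * r * cos(theta), r^2)),
                          rnorm(n))
    m <- broad / sd(broad) + 2 * res / sd(res)
    m <- m / sd(m)
    boost <- 1 + 0.9 * as.numeric(stats::filter(sys_ind, rep(1 / 480, 480),
                                                sides = 2))
    boost[is.na(boost)] <- 1
    side_gain <- if (side == "R") profile$side_asymmetry else 1
    x <- x + profile$murmur_gain * side_gain * m * boost
    x <- x + rnorm(n, 0, 0.04)
    if (device_gain_db != 0) x <- x * 10^(device_gain_db / 20)
    if (!is.null(device_lp_hz)) {
      lf <- signal::butter(1, device_lp_hz / (fs / 2), type = "low")
      x <- signal::filtfilt(lf, x)
    }
    x <- x / max(abs(x))
    truth <- do.call(rbind, spans)
    truth$start_sample <- floor(truth$t0 * fs) + 1L
    truth$end_sample <- floor(truth$t1 * fs)
    truth <- truth[truth$end_sample >= 1 & truth$start_sample <= n, ]
    truth$start_sample <- pmax(1L, truth$start_sample)
    truth$end_sample <- pmin(n, truth$end_sample)
    truth <- truth[truth$end_sample >= truth$start_sample,
                   c("start_sample", "end_sample", "state")]
    # the interval before the first simulated cycle is late diastole
    if (nrow(truth) > 0 && truth$start_sample[1] > 1)
      truth <- rbind(data.frame(start_sample = 1L,
                                end_sample = truth$start_sample[1] - 1L,
                                state = "diastole"), truth)
    rownames(truth) <- NULL
    structure(list(samples = x, fs = fs, duration = duration,
                   user_id = user_id, device_id = device_id, side = side,
                   low_quality = low_quality, truth_states = truth),
              class = "carotid_recording")
  })
}

#' @export
print.carotid_recording <- function(x, ...) {
  cat(sprintf("<carotid_recording %s %s %s: %.1f s @ %d Hz, %d samples>\n",
              x$user_id %||% "?", x$device_id %||% "?", x$side %||% "?",
              x$duration, x$fs, length(x$samples)))
  invisible(x)
}

# Deterministic low-quality flag assignment for a dataset of n recordings.
assign_quality_flags <- function(n, fraction, seed) {
  with_seed(seed, runif(n) < fraction)
}

device_params <- function(devices) {
  gains <- c(-2, -1, 1, 2)
  lps <- c(6000, 5000, 4000, 3000)
  k <- seq_along(devices)
  data.frame(device = devices,
             gain_db = gains[((k - 1) %% 4) + 1],
             lp_hz = lps[((k - 1) %% 4) + 1],
             stringsAsFactors = FALSE)
}

#' Simulate a dataset of carotid recordings on disk
#'
#' Writes one WAV per recording, one ground-truth state CSV per recording,
#' and a `manifest.csv` with columns `path,user,device,side,quality`.
#' Devices are modeled as clones differing by a +/-2 dB gain and a gentle
#' first-order low-pass.
#'
#' @param profiles list of `carotid_profile`.
#' @param per_user recordings per user (scalar or vector per user).
#' @param devices,sides label vocabularies cycled over recordings.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; the dataset is byte-reproducible given it.
#' @param low_quality_fraction expected fraction of degraded recordings
#'   (default calibrated to a 9/890 rejection rate).
#' @param duration,fs recording length (s) and sampling rate (Hz).
#' @return the manifest data.frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
simulate_dataset <- function(profiles, per_user = 20,
                             devices = paste0("D", 1:4),
                             sides = c("L", "R"), out_dir, seed = 1,
                             low_quality_fraction = 9 / 890,
                             duration = 11, fs = 16000) {
  stopifnot(length(profiles) >= 1, all(per_user > 0))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  counts <- rep_len(as.integer(per_user), length(profiles))
  total <- sum(counts)
  flags <- assign_quality_flags(total, low_quality_fraction,
                                derive_seed(seed, 0))
  dev <- device_params(devices)
  rows <- list()
  r <- 0L
  for (u in seq_along(profiles)) {
    for (j in seq_len(counts[u])) {
      r <- r + 1L
      d <- ((j - 1L) %% nrow(dev)) + 1L
      s <- sides[((j - 1L) %% length(sides)) + 1L]
      rec <- simulate_recording(profiles[[u]], duration = duration, fs = fs,
                                seed = derive_seed(seed, r),
                                low_quality = flags[r], side = s,
                                device_gain_db = dev$gain_db[d],
                                device_lp_hz = dev$lp_hz[d],
                                device_id = dev$device[d])
      base <- sprintf("%s_%s_%s_%03d", profiles[[u]]$user_id, dev$device[d],
                      s, j)
      wav <- file.path(out_dir, paste0(base, ".wav"))
      write_wav(rec$samples, fs, wav)
      write.csv(rec$truth_states,
                file.path(out_dir, paste0(base, "_states.csv")),
                row.names = FALSE)
      rows[[r]] <- data.frame(path = wav, user = profiles[[u]]$user_id,
                              device = dev$device[d], side = s,
                              quality = ifelse(flags[r], "low", "good"),
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
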