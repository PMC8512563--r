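# Cardiac state segmentation with a duration-dependent (hidden semi-Markov)
# model.  Four envelope features at a 50 Hz frame rate feed one-vs-rest
# logistic-regression emission models; state durations are truncated-Normal
# and the transition structure is the fixed cardiac cycle
# S1 -> systole -> S2 -> diastole -> S1.  Decoding is an extended Viterbi
# over explicit segment durations.  The first and last segments of a
# recording are scored with the duration survival function, since recordings
# start and end mid-state.

HS_STATES <- c("S1", "systole", "S2", "diastole")
HS_PREV <- c(4L, 1L, 2L, 3L)   # cyclic predecessor of each state

#' Envelope features for heart-sound segmentation
#'
#' Computes four envelopes on a 25-400 Hz band-passed copy of the signal,
#' decimated to ~1 kHz: the homomorphic envelope (low-passed log magnitude),
#' the Hilbert envelope, a Morse-wavelet envelope at 60 Hz, and a 40-60 Hz
#' power-band envelope.  Each is block-averaged to the frame rate and
#' min-max scaled to \[0, 1\] per recording.
#'
#' @param rec a `carotid_recording` with `fs >= 1000`.
#' @param frame_rate output frame rate, Hz.
#' @return matrix (n_frames x 4) with attributes `frame_rate` and `fs_audio`.
#' @export
extract_features <- function(rec, frame_rate = 50) {
  stopifnot(inherits(rec, "carotid_recording"))
  if (rec$fs < 1000) stop("fs must be >= 1000 Hz")
  if (rec$duration < 2) stop("recording shorter than 2 s")
  fs <- rec$fs
  bf <- signal::butter(4, c(25, 400) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, rec$samples)
  dec <- max(1L, floor(fs / 1000))
  xd <- xb[seq(1, length(xb), by = dec)]
  fs1 <- fs / dec
  he <- Mod(analytic_signal(xd))
  lf <- signal::butter(1, 8 / (fs1 / 2), type = "low")
  # normalizing before the log makes the envelope (and hence the
  # segmentation) exactly invariant to overall amplitude
  hom <- exp(signal::filtfilt(lf, log(he / max(he) + 1e-9)))
  # single-scale Morse filter at 60 Hz
  m <- nextn(length(xd), c(2, 3, 5))
  X <- fft(c(xd, numeric(m - length(xd))))
  half <- 0:(m %/% 2)
  p <- morse_params()
  s <- morse_peak_frequency(p) * fs1 / (2 * pi * 60)
  psi <- morse_window(s * 2 * pi * half / m, p)
  Y <- complex(length.out = m)
  Y[half + 1L] <- X[half + 1L] * psi
  we <- Mod(fft(Y, inverse = TRUE)[seq_along(xd)] / m)
  pf <- signal::butter(3, c(40, 60) / (fs1 / 2), type = "pass")
  pe <- moving_average(Mod(analytic_signal(signal::filtfilt(pf, xd))),
                       round(0.05 * fs1))
  b <- round(fs1 / frame_rate)
  feats <- cbind(homomorphic = block_mean(hom, b),
                 hilbert = block_mean(he, b),
                 wavelet = block_mean(we, b),
                 psd = block_mean(pe, b))
  rng <- apply(feats, 2, range)
  if (any(rng[2, ] - rng[1, ] <= 0))
    stop("degenerate input: constant envelope feature")
  feats <- sweep(sweep(feats, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  attr(feats, "frame_rate") <- frame_rate
  attr(feats, "fs_audio") <- fs
  class(feats) <- c("hs_features", class(feats))
  feats
}

#' Ground-truth cardiac states at frame resolution
#'
#' Maps a recording's sample-level truth spans to per-frame labels (state at
#' each frame center), for training and scoring the segmenter.
#'
#' @param rec a `carotid_recording` with `truth_states`.
#' @param frame_rate frames per second.
#' @param n_frames optional frame count (defaults to the full recording).
#' @return factor of length `n_frames` with levels S1, systole, S2, diastole.
#' @export
truth_frame_states <- function(rec, frame_rate = 50, n_frames = NULL) {
  stopifnot(!is.null(rec$truth_states))
  hop <- rec$fs / frame_rate
  if (is.null(n_frames)) n_frames <- floor(length(rec$samples) / hop)
  centers <- round((seq_len(n_frames) - 0.5) * hop)
  ts <- rec$truth_states
  idx <- findInterval(centers, ts$start_sample)
  idx[idx < 1] <- 1
  factor(ts$state[idx], levels = HS_STATES)
}

#' Estimate heart rate from segmentation features
#'
#' Autocorrelation of the homomorphic envelope; the peak lag is searched in
#' \[0.43, 1.5\] s (40-140 bpm).  Falls back to a 70 bpm prior, with a
#' warning, when the envelope shows no periodicity.
#'
#' @param features an `hs_features` matrix.
#' @param prior fallback heart rate, bpm.
#' @return heart rate in beats/min.
#' @export
estimate_heart_rate <- function(features, prior = 70) {
  frame_rate <- attr(features, "frame_rate") %||% 50
  if (nrow(features) < 5 * frame_rate)
    stop("need at least 5 s of frames to estimate heart rate")
  hr_from_envelope(features[, "homomorphic"], frame_rate, prior = prior)
}

#' Fit the duration-dependent segmentation model
#'
#' One-vs-rest logistic regressions on the four envelope features (emission
#' model) and truncated-Normal duration distributions estimated from labeled
#' run lengths.  Boundary runs of each recording are excluded from duration
#' estimation (they are truncated by the recording edges).
#'
#' @param training list of `list(features = <hs_features>,
#'   states = <factor per frame>)`, at least 10 recordings.
#' @return an `hsmm_model`.
#' @export
fit_hsmm <- function(training) {
  if (length(training) < 10)
    stop("need at least 10 labeled recordings")
  feats <- do.call(rbind, lapply(training, function(tr) unclass(tr$features)))
  labs <- unlist(lapply(training, function(tr) as.character(tr$states)))
  missing <- setdiff(HS_STATES, unique(labs))
  if (length(missing))
    stop("state(s) absent from training labels: ",
         paste(missing, collapse = ", "))
  X <- cbind(1, feats[, 1:4, drop = FALSE])
  W <- sapply(HS_STATES, function(s) {
    fit <- suppressWarnings(
      glm.fit(X, as.numeric(labs == s), family = binomial()))
    fit$coefficients
  })
  durs <- lapply(HS_STATES, function(s) numeric(0))
  names(durs) <- HS_STATES
  for (tr in training) {
    r <- rle(as.character(tr$states))
    if (length(r$lengths) <= 2) next
    keep <- 2:(length(r$lengths) - 1)   # interior runs only
    for (i in keep)
      durs[[r$values[i]]] <- c(durs[[r$values[i]]], r$lengths[i])
  }
  dur_tab <- data.frame(
    state = HS_STATES,
    mean = vapply(durs[HS_STATES], function(d) mean(d), 0),
    sd = vapply(durs[HS_STATES],
                function(d) max(0.5, if (length(d) > 1) sd(d) else 0.5), 0))
  frame_rate <- attr(training[[1]]$features, "frame_rate") %||% 50
  structure(list(weights = W, durations = dur_tab, frame_rate = frame_rate),
            class = "hsmm_model")
}

# Duration pmf and survival (log scale) over integer support [1, dmax];
# pmf mass restricted to [dmin, dmax], survival is 0 (log 1) below dmin.
duration_logprobs <- function(mean, sd, dmin, dmax) {
  d <- seq_len(dmax)
  lp <- rep(-Inf, dmax)
  sup <- d >= dmin
  lp[sup] <- dnorm(d[sup], mean, sd, log = TRUE)
  lse <- max(lp[sup]) + log(sum(exp(lp[sup] - max(lp[sup]))))
  lp <- lp - lse
  p <- exp(lp)
  surv <- log(pmin(1, rev(cumsum(rev(p)))))
  list(logpmf = lp, logsurv = surv, dmin = dmin, dmax = dmax)
}

# Extended Viterbi over explicit segment durations with fixed cyclic
# transitions.  logem: T x 4 frame log-likelihoods; durp: list of 4
# duration_logprobs.  First/last segments are scored by survival.
# Returns the integer state path (1..4 indexing HS_STATES).
viterbi_core <- function(logem, durp) {
  T_ <- nrow(logem)
  S <- ncol(logem)
  cum <- rbind(0, apply(logem, 2, cumsum))   # cum[t+1, j]
  V <- matrix(-Inf, T_, S)
  ptr_d <- matrix(0L, T_, S)
  ptr_first <- matrix(FALSE, T_, S)
  for (t in seq_len(T_)) {
    for (j in seq_len(S)) {
      dp <- durp[[j]]
      best <- -Inf; bd <- 0L; bfirst <- FALSE
      # interior segment: starts after a predecessor segment
      dmaxj <- min(t - 1L, dp$dmax)
      if (dmaxj >= dp$dmin) {
        d <- dp$dmin:dmaxj
        val <- cum[t + 1L, j] - cum[t - d + 1L, j] + dp$logpmf[d] +
          V[t - d, HS_PREV[j]]
        k <- which.max(val)
        if (val[k] > best) { best <- val[k]; bd <- d[k]; bfirst <- FALSE }
      }
      # segment starting at frame 1 (left-truncated): survival scoring
      if (t <= dp$dmax) {
        val <- cum[t + 1L, j] - cum[1L, j] + dp$logsurv[t]
        if (val > best) { best <- val; bd <- t; bfirst <- TRUE }
      }
      V[t, j] <- best; ptr_d[t, j] <- bd; ptr_first[t, j] <- bfirst
    }
  }
  # final segment ends at T_ and is right-truncated: survival scoring
  best <- -Inf; bj <- 1L; bd <- 0L; bfirst <- FALSE
  for (j in seq_len(S)) {
    dp <- durp[[j]]
    dmaxj <- min(T_ - 1L, dp$dmax)
    if (dmaxj >= 1L) {
      d <- seq_len(dmaxj)
      val <- cum[T_ + 1L, j] - cum[T_ - d + 1L, j] + dp$logsurv[d] +
        V[T_ - d, HS_PREV[j]]
      k <- which.max(val)
      if (val[k] > best) { best <- val[k]; bj <- j; bd <- d[k]; bfirst <- FALSE }
    }
    if (T_ <= dp$dmax) {
      val <- cum[T_ + 1L, j] - cum[1L, j] + dp$logsurv[T_]
      if (val > best) { best <- val; bj <- j; bd <- T_; bfirst <- TRUE }
    }
  }
  path <- integer(T_)
  t <- T_; j <- bj; d <- bd; first <- bfirst
  repeat {
    path[(t - d + 1L):t] <- j
    if (first || t - d <= 0L) break
    t <- t - d
    j <- HS_PREV[j]
    d <- ptr_d[t, j]
    first <- ptr_first[t, j]
  }
  path
}

#' Segment a recording into cardiac states
#'
#' Maximum a-posteriori state path under the logistic emission model,
#' cyclic transitions and explicit duration densities.  Systole and
#' diastole duration means are rescaled so the expected cycle length
#' matches the (estimated) heart rate; S1/S2 durations are kept from
#' training.  The duration search is capped at twice each state's mean.
#'
#' @param features an `hs_features` matrix.
#' @param model an `hsmm_model`.
#' @param heart_rate beats/min; estimated from `features` when `NULL`.
#' @return a `state_sequence`: list with `frames` (factor), `frame_rate`,
#'   `fs_audio`, `heart_rate`.
#' @export
viterbi_segment <- function(features, model, heart_rate = NULL) {
  stopifnot(inherits(model, "hsmm_model"))
  if (is.null(heart_rate)) heart_rate <- estimate_heart_rate(features)
  fr <- model$frame_rate
  dt <- model$durations
  m <- structure(dt$mean, names = dt$state)
  s <- structure(dt$sd, names = dt$state)
  total <- fr * 60 / heart_rate
  f <- (total - m["S1"] - m["S2"]) / (m["systole"] + m["diastole"])
  f <- max(0.3, f)
  m[c("systole", "diastole")] <- m[c("systole", "diastole")] * f
  s[c("systole", "diastole")] <- pmax(0.5, s[c("systole", "diastole")] * f)
  durp <- lapply(HS_STATES, function(st) {
    dmin <- max(2L, floor(0.25 * m[st]))
    dmax <- max(dmin + 1L, ceiling(2 * m[st]))
    duration_logprobs(m[st], s[st], dmin, dmax)
  })
  if (nrow(features) < sum(vapply(durp, `[[`, 0, "dmin")))
    stop("too few frames for one cardiac cycle")
  eta <- cbind(1, unclass(features)[, 1:4, drop = FALSE]) %*% model$weights
  P <- plogis(eta)
  P <- P / rowSums(P)
  logem <- log(pmax(P, 1e-12))
  path <- viterbi_core(logem, durp)
  structure(list(frames = factor(HS_STATES[path], levels = HS_STATES),
                 frame_rate = fr,
                 fs_audio = attr(features, "fs_audio"),
                 heart_rate = heart_rate),
            class = "state_sequence")
}

#' Extract cardiac-cycle boundaries from a state sequence
#'
#' One cycle spans from the start of a diastole run to the end of the next
#' S2 run (diastole, S1, systole, S2).  Incomplete leading or trailing
#' fragments are discarded; an empty result is returned (not an error) when
#' no complete cycle exists.
#'
#' @param states a `state_sequence`, or a factor/character vector of frame
#'   labels (in which case boundaries are in frame units).
#' @param fs target sample rate for the boundaries; defaults to the
#'   recording rate stored in `states` (or 1 for plain label vectors).
#' @return data.frame with `start_sample`, `end_sample`, non-overlapping
#'   and increasing.
#' @export
extract_cycles <- function(states, fs = NULL) {
  if (inherits(states, "state_sequence")) {
    hop <- (fs %||% states$fs_audio %||% states$frame_rate) /
      states$frame_rate
    labs <- as.character(states$frames)
  } else {
    hop <- fs %||% 1
    labs <- as.character(states)
  }
  r <- rle(labs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] != "diastole" || i + 3L > length(r$values)) next
    if (!identical(r$values[i + 1:3], c("S1", "systole", "S2"))) next
    out[[length(out) + 1L]] <- data.frame(
      start_sample = round((starts[i] - 1L) * hop) + 1L,
      end_sample = round(ends[i + 3L] * hop))
  }
  if (!length(out))
    return(data.frame(start_sample = integer(0), end_sample = integer(0)))
  do.call(rbind, out)
}
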