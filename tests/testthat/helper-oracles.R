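# Independent oracles.

# Brute-force decoder for the duration-dependent model: enumerate every
# label sequence whose runs follow the cyclic order S1 -> systole -> S2 ->
# diastole, score it with the same objective as the dynamic program
# (truncated-Normal duration pmf for interior segments, survival for the
# first and last segments), and return the best path.
brute_force_decode <- function(logem, durp) {
  T_ <- nrow(logem)
  S <- ncol(logem)
  nxt <- c(2L, 3L, 4L, 1L)
  cum <- rbind(0, apply(logem, 2, cumsum))
  best <- list(score = -Inf, path = NULL)
  recurse <- function(t, state, segs) {
    # segs: list of c(state, start, end)
    for (d in seq_len(T_ - t + 1L)) {
      end <- t + d - 1L
      seg <- c(state, t, end)
      if (end == T_) {
        all_segs <- c(segs, list(seg))
        score <- 0
        M <- length(all_segs)
        for (m in seq_len(M)) {
          sg <- all_segs[[m]]
          dlen <- sg[3] - sg[2] + 1L
          dp <- durp[[sg[1]]]
          score <- score + cum[sg[3] + 1L, sg[1]] - cum[sg[2], sg[1]]
          if (m == 1L || m == M) {
            if (dlen > dp$dmax) { score <- -Inf; break }
            score <- score + dp$logsurv[dlen]
          } else {
            if (dlen < dp$dmin || dlen > dp$dmax) { score <- -Inf; break }
            score <- score + dp$logpmf[dlen]
          }
        }
        if (score > best$score) {
          path <- integer(T_)
          for (sg in all_segs) path[sg[2]:sg[3]] <- sg[1]
          best <<- list(score = score, path = path)
        }
      } else {
        recurse(end + 1L, nxt[state], c(segs, list(seg)))
      }
    }
  }
  for (s0 in seq_len(S)) recurse(1L, s0, list())
  best
}

# Random toy decoding instance: <= max_frames frames, 4 states, random
# emissions and random truncated-Normal durations.
random_toy_instance <- function(seed, max_frames = 12) {
  set.seed(seed)
  T_ <- sample(4:max_frames, 1)
  logem <- matrix(log(runif(T_ * 4, 0.05, 1)), T_, 4)
  durp <- lapply(1:4, function(j) {
    dmin <- sample(1:2, 1)
    dmax <- dmin + sample(1:4, 1)
    carotidprint:::duration_logprobs(runif(1, dmin, dmax), runif(1, 0.5, 2),
                                     dmin, dmax)
  })
  list(logem = logem, durp = durp)
}

# Brute-force threshold sweep: is there a scalar threshold separating the
# two groups of feature values perfectly?
threshold_separable <- function(a, b) {
  for (thr in sort(c(a, b))) {
    if ((all(a <= thr) && all(b > thr)) || (all(b <= thr) && all(a > thr)))
      return(TRUE)
  }
  FALSE
}

# Log-frequency spectral centroid of a recording inside a band (Hz): the
# band-energy summary used to check murmur-band separability.
band_centroid <- function(rec, f_lo = 4, f_hi = 100) {
  n <- length(rec$samples)
  P <- Mod(fft(rec$samples))^2
  f <- (seq_len(n) - 1) * rec$fs / n
  keep <- f >= f_lo & f <= f_hi
  sum(log2(f[keep]) * P[keep]) / sum(P[keep])
}
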