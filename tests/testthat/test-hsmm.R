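test_that("features have the expected frame count and range", {
  rec <- fix_clean_rec()
  fe <- extract_features(rec)
  expect_equal(ncol(fe), 4)
  expect_true(abs(nrow(fe) - 550) <= 1)
  expect_gte(min(fe), 0)
  expect_lte(max(fe), 1)
  zero <- structure(list(samples = numeric(48000), fs = 16000, duration = 3),
                    class = "carotid_recording")
  expect_error(extract_features(zero), "degenerate")
})

test_that("the homomorphic envelope peaks inside true S1 spans", {
  rec <- fix_clean_rec()
  fe <- extract_features(rec)
  truth <- truth_frame_states(rec, n_frames = nrow(fe))
  # within each interior cardiac cycle, the frame of maximal homomorphic
  # envelope should be S1 or its immediate neighbor
  r <- rle(as.character(truth))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  s1_runs <- which(r$values == "S1")
  s1_runs <- s1_runs[s1_runs > 1 & s1_runs < length(r$values) - 2]
  hits <- 0
  for (i in s1_runs[1:5]) {
    lo <- starts[i] - 2; hi <- ends[i] + 2
    win <- max(1, starts[i] - 8):min(nrow(fe), ends[i] + 8)
    pk <- win[which.max(fe[win, "homomorphic"])]
    hits <- hits + (pk >= lo && pk <= hi)
  }
  expect_gte(hits, 4)
})

test_that("heart rate is recovered within tolerance and falls back on noise", {
  fe60 <- extract_features(simulate_recording(profile_with_hr(60), seed = 11))
  expect_equal(estimate_heart_rate(fe60), 60, tolerance = 3 / 60)
  fe100 <- extract_features(simulate_recording(profile_with_hr(100), seed = 12))
  expect_equal(estimate_heart_rate(fe100), 100, tolerance = 5 / 100)
  # white noise: no cardiac periodicity -> prior + warning
  noise <- structure(list(samples = {
    set.seed(9); x <- rnorm(11 * 16000); x / max(abs(x))
  }, fs = 16000, duration = 11), class = "carotid_recording")
  fe_n <- extract_features(noise)
  expect_warning(hr <- estimate_heart_rate(fe_n), "prior")
  expect_equal(hr, 70)
})

test_that("model fitting is deterministic and validates its inputs", {
  expect_error(fit_hsmm(list()), "at least 10")
  profiles <- fix_profiles()
  training <- lapply(1:10, function(i) {
    rec <- simulate_recording(profiles[[(i - 1) %% 7 + 1]], seed = 400 + i)
    fe <- extract_features(rec)
    list(features = fe, states = truth_frame_states(rec, n_frames = nrow(fe)))
  })
  m1 <- fit_hsmm(training)
  m2 <- fit_hsmm(training)
  expect_identical(m1, m2)
  expect_setequal(m1$durations$state, c("S1", "systole", "S2", "diastole"))
  expect_true(all(m1$durations$mean > 0))
  # drop all S2 labels -> named fit error
  broken <- lapply(training, function(tr) {
    tr$states[tr$states == "S2"] <- "systole"
    tr$states <- factor(as.character(tr$states),
                        levels = c("S1", "systole", "S2", "diastole"))
    tr
  })
  expect_error(fit_hsmm(broken), "S2")
})

test_that("duration-dependent Viterbi matches brute-force enumeration", {
  ok <- vapply(1:100, function(i) {
    inst <- random_toy_instance(i)
    dp <- carotidprint:::viterbi_core(inst$logem, inst$durp)
    bf <- brute_force_decode(inst$logem, inst$durp)
    identical(dp, bf$path)
  }, TRUE)
  expect_true(all(ok))
})

test_that("sharply peaked durations recover truth under flat emissions", {
  # uniform emissions; durations almost surely 2 frames per state
  T_ <- 16
  logem <- matrix(0, T_, 4)
  durp <- lapply(1:4, function(j)
    carotidprint:::duration_logprobs(2, 0.05, 2, 3))
  path <- carotidprint:::viterbi_core(logem, durp)
  r <- rle(path)
  # interior segments must hit the duration mode exactly; the first and
  # last segments may be truncated by the recording edges
  interior <- r$lengths[-c(1, length(r$lengths))]
  expect_true(all(interior == 2))
  expect_true(all(r$lengths <= 3))
  # cyclic order preserved
  nxt <- c(2L, 3L, 4L, 1L)
  for (i in seq_len(length(r$values) - 1))
    expect_identical(r$values[i + 1], nxt[r$values[i]])
})

test_that("segmentation is invariant to overall amplitude", {
  rec <- fix_clean_rec()
  half <- rec
  half$samples <- 0.5 * rec$samples
  m <- fix_hsmm()
  s1 <- viterbi_segment(extract_features(rec), m)
  s2 <- viterbi_segment(extract_features(half), m)
  expect_identical(s1$frames, s2$frames)
})

test_that("cycle extraction applies the diastole-to-S2 rule literally", {
  lab <- c("diastole", "S1", "systole", "S2", "diastole", "S1", "systole",
           "S2")
  cyc <- extract_cycles(lab)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$start_sample, c(1, 5))
  expect_equal(cyc$end_sample, c(4, 8))
  expect_equal(nrow(extract_cycles(c("S1", "systole", "S2", "diastole"))), 0)
})

test_that("cycle count never exceeds the number of S2 runs", {
  m <- fix_hsmm()
  for (u in c(2, 6)) {
    rec <- simulate_recording(fix_profiles()[[u]], seed = 550 + u)
    ss <- viterbi_segment(extract_features(rec), m)
    cyc <- extract_cycles(ss, fs = rec$fs)
    n_s2 <- sum(rle(as.character(ss$frames))$values == "S2")
    expect_lte(nrow(cyc), n_s2)
    expect_true(all(diff(cyc$start_sample) > 0))
    expect_true(all(cyc$end_sample > cyc$start_sample))
    expect_true(all(cyc$start_sample[-1] > head(cyc$end_sample, -1)))
  }
})
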