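# Shared fixtures, memoised per test session (several are expensive to
# build: labeled recordings, a fitted segmenter, the end-to-end report).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

fix_profiles <- function() memo("profiles", make_profiles(7, seed = 1,
                                                          separation = 0.8))

# A profile with a prescribed mean heart rate (for timing-sensitive tests).
profile_with_hr <- function(hr, base = fix_profiles()[[1]]) {
  p <- base
  p$hr_mean <- hr
  p$hr_sd <- 2
  p
}

fix_clean_rec <- function() memo("clean_rec",
  simulate_recording(fix_profiles()[[1]], seed = 42))

# Segmenter trained on 21 clean labeled recordings spanning all users
# (criterion: held-out frame accuracy of the duration-dependent decoder).
fix_hsmm <- function() memo("hsmm", {
  profiles <- fix_profiles()
  training <- list()
  for (u in 1:7) {
    for (j in 1:3) {
      rec <- simulate_recording(profiles[[u]], seed = 3000 + u * 10 + j)
      fe <- extract_features(rec)
      training[[length(training) + 1L]] <-
        list(features = fe,
             states = truth_frame_states(rec, n_frames = nrow(fe)))
    }
  }
  fit_hsmm(training)
})

# The full left-side identification experiment at the study scale
# (7 users, 9 recordings each, 5-fold x 2 repetitions).
fix_e2e_report <- function() memo("e2e", {
  cfg <- pipeline_config(n_users = 7, separation = 0.8,
                         recordings_per_user = 9, sides = "L", seed = 1,
                         cv_k = 5, cv_repetitions = 2,
                         cnn = cnn_config(n_classes = 7), verbose = FALSE)
  run_pipeline(cfg)
})

# Tiny rendered-image set for CNN plumbing tests: two trivially separable
# classes of constant images.
fix_constant_images <- function(n_per_class = 40) memo("const_imgs", {
  imgs <- c(lapply(seq_len(n_per_class), function(i) array(0.2, c(134, 134, 3))),
            lapply(seq_len(n_per_class), function(i) array(0.8, c(134, 134, 3))))
  list(images = imgs, labels = rep(c("A", "B"), each = n_per_class))
})
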