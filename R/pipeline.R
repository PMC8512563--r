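# End-to-end orchestration: simulate -> quality screen -> segment -> CWT ->
# cycle images / fingerprints -> CNN cross-validation -> report.
# Left and right sides are processed as independent experiments.

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end experiment.  Unknown arguments
#' are rejected.  `analysis_fs` is the rate the audio is decimated to before
#' the fingerprint CWT (the analysis band tops out at `f_max` Hz, so 2 kHz
#' retains a five-fold oversampling margin); segmentation and quality
#' screening always run on the native-rate audio.
#'
#' @param n_users simulated subjects.
#' @param separation murmur-band spacing request, octaves (see
#'   [make_profiles()]).
#' @param recordings_per_user recordings per user per side.
#' @param sides sides to simulate and analyze (`"L"`, `"R"` or both).
#' @param duration,fs recording length (s) and audio rate (Hz).
#' @param seed master seed for simulation, CV and training.
#' @param profile_seed seed for the subject profiles.
#' @param low_quality_fraction expected degraded-recording fraction.
#' @param quality_screen reject low-quality recordings before analysis
#'   (`FALSE` bypasses the screen; identification does not depend on it).
#' @param hsmm_train_per_user labeled training recordings per user for the
#'   segmenter (held out from the analysis set).
#' @param analysis_fs decimated rate for the fingerprint CWT, Hz.
#' @param f_min,f_max,voices_per_octave CWT analysis band and resolution.
#' @param image_size classifier image side length.
#' @param target_len resized cycle length, columns.
#' @param cv_k,cv_repetitions cross-validation plan.
#' @param cnn a `cnn_config` (its `n_classes` must equal `n_users`).
#' @param keep_images retain rendered images in the returned object.
#' @param verbose print stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_users = 7, separation = 0.8,
                            recordings_per_user = 9, sides = "L",
                            duration = 11, fs = 16000, seed = 1,
                            profile_seed = 1,
                            low_quality_fraction = 9 / 890,
                            quality_screen = TRUE,
                            hsmm_train_per_user = 2,
                            analysis_fs = 2000, f_min = 1, f_max = 200,
                            voices_per_octave = 10,
                            image_size = 134, target_len = 16000,
                            cv_k = 5, cv_repetitions = 2,
                            cnn = cnn_config(n_classes = n_users),
                            keep_images = FALSE, verbose = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Decimate audio by an integer factor with an anti-alias low-pass.
resample_audio <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  r <- fs / target_fs
  if (r != round(r)) stop("fs must be an integer multiple of target_fs")
  lf <- signal::butter(8, 0.8 / r, type = "low")
  signal::filtfilt(lf, x)[seq(1, length(x), by = r)]
}

#' Run the full identification pipeline
#'
#' Simulates the configured dataset in memory, screens quality, segments
#' cardiac cycles with an HSMM trained on a held-out labeled set, computes
#' Morse-wavelet spectra, renders per-cycle images, runs the CNN under
#' stratified repeated k-fold cross-validation separately per side, and
#' aggregates metrics.
#'
#' @param cfg a `pipeline_config`.
#' @return a `carotid_cv_report`: per-side confusion matrices, aggregated
#'   metrics, mean normalized confusion matrix, mean multiclass accuracy
#'   (percent), per-user/side fingerprints and cycle counts.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  msg <- function(...) if (cfg$verbose) message(sprintf(...))
  if (cfg$n_users < 2) stop("need >= 2 classes")
  profiles <- make_profiles(cfg$n_users, seed = cfg$profile_seed,
                            separation = cfg$separation)

  msg("Training segmenter on %d labeled recordings",
      cfg$n_users * cfg$hsmm_train_per_user)
  training <- list()
  for (u in seq_len(cfg$n_users)) {
    for (j in seq_len(cfg$hsmm_train_per_user)) {
      rec <- simulate_recording(profiles[[u]], duration = cfg$duration,
                                fs = cfg$fs,
                                seed = derive_seed(cfg$seed, 90000 + u * 100 + j))
      fe <- extract_features(rec)
      training[[length(training) + 1L]] <-
        list(features = fe,
             states = truth_frame_states(rec, n_frames = nrow(fe)))
    }
  }
  model <- fit_hsmm(training)

  dev <- device_params(paste0("D", 1:4))
  n_total <- cfg$n_users * cfg$recordings_per_user * length(cfg$sides)
  flags <- assign_quality_flags(n_total, cfg$low_quality_fraction,
                                derive_seed(cfg$seed, 0))
  msg("Simulating %d recordings (%d flagged low quality)", n_total,
      sum(flags))
  specs <- list()
  r <- 0L
  for (u in seq_len(cfg$n_users)) {
    for (s in cfg$sides) {
      for (j in seq_len(cfg$recordings_per_user)) {
        r <- r + 1L
        d <- ((j - 1L) %% nrow(dev)) + 1L
        specs[[r]] <- list(u = u, side = s, j = j, d = d, flag = flags[r],
                           seed = derive_seed(cfg$seed, r))
      }
    }
  }

  images <- list(); img_user <- character(0); img_side <- character(0)
  fp_sum <- list(); fp_n <- list()
  quality_rows <- list()
  n_freqs <- floor(cfg$voices_per_octave * log2(cfg$f_max / cfg$f_min)) + 1L
  for (sp in specs) {
    rec <- simulate_recording(profiles[[sp$u]], duration = cfg$duration,
                              fs = cfg$fs, seed = sp$seed,
                              low_quality = sp$flag, side = sp$side,
                              device_gain_db = dev$gain_db[sp$d],
                              device_lp_hz = dev$lp_hz[sp$d],
                              device_id = dev$device[sp$d])
    qr <- assess_quality(rec)
    quality_rows[[length(quality_rows) + 1L]] <- data.frame(
      user = rec$user_id, side = sp$side, flagged_low = sp$flag,
      n_expected = qr$n_expected_cycles, n_s1 = qr$n_s1_detected,
      n_s2 = qr$n_s2_detected, pass = qr$pass)
    if (cfg$quality_screen && !qr$pass) next
    fe <- extract_features(rec)
    states <- viterbi_segment(fe, model)
    cycles <- extract_cycles(states, fs = cfg$fs)
    if (!nrow(cycles)) next
    xd <- resample_audio(rec$samples, cfg$fs, cfg$analysis_fs)
    spec <- compute_cwt(xd, fs = cfg$analysis_fs,
                        voices_per_octave = cfg$voices_per_octave,
                        f_min = cfg$f_min, f_max = cfg$f_max)
    segs <- segment_spectrum(spec, cycles, cycles_fs = cfg$fs)
    key <- paste(rec$user_id, sp$side, sep = "-")
    for (m in segs) {
      rm_ <- resize_cycle(m, cfg$target_len)
      images[[length(images) + 1L]] <-
        render_cycle_image(rm_, size = cfg$image_size)
      img_user <- c(img_user, rec$user_id)
      img_side <- c(img_side, sp$side)
      if (is.null(fp_sum[[key]])) {
        fp_sum[[key]] <- rm_
        fp_n[[key]] <- 1L
      } else {
        fp_sum[[key]] <- fp_sum[[key]] + rm_
        fp_n[[key]] <- fp_n[[key]] + 1L
      }
    }
  }
  quality <- do.call(rbind, quality_rows)
  msg("Rendered %d cycle images", length(images))

  fingerprints <- lapply(names(fp_sum), function(k) {
    fp <- fp_sum[[k]] / fp_n[[k]]
    attr(fp, "n_cycles") <- fp_n[[k]]
    class(fp) <- c("carotid_fingerprint", class(fp))
    fp
  })
  names(fingerprints) <- names(fp_sum)

  X <- images_to_matrix(images)
  by_side <- list()
  for (s in cfg$sides) {
    idx <- which(img_side == s)
    labels <- factor(img_user[idx])
    msg("Side %s: %d images, %d classes; %d-fold x %d repetitions", s,
        length(idx), nlevels(labels), cfg$cv_k, cfg$cv_repetitions)
    splits <- make_cv_splits(labels, k = cfg$cv_k,
                             repetitions = cfg$cv_repetitions,
                             seed = derive_seed(cfg$seed, 5000))
    Xs <- X[, idx, drop = FALSE]
    attr(Xs, "img_dim") <- attr(X, "img_dim")
    cms <- train_and_eval(Xs, labels, splits, cfg$cnn,
                          seed = derive_seed(cfg$seed, 6000))
    runs <- lapply(cms, confusion_to_metrics)
    by_side[[s]] <- list(
      confusions = cms,
      metrics = runs,
      aggregate = aggregate_runs(runs),
      normalized_confusion = normalize_confusion(cms),
      mean_accuracy_pct = 100 * cv_mean_accuracy(cms))
    msg("Side %s mean accuracy: %.2f%%", s,
        by_side[[s]]$mean_accuracy_pct)
  }

  out <- list(config = cfg, quality = quality,
              n_images = length(images),
              cycle_counts = table(user = img_user, side = img_side),
              fingerprints = fingerprints,
              sides = by_side)
  if (cfg$keep_images) {
    out$images <- images
    out$image_user <- img_user
    out$image_side <- img_side
  }
  class(out) <- "carotid_cv_report"
  out
}

#' @export
print.carotid_cv_report <- function(x, ...) {
  cat("Carotid-sound identification report\n")
  cat(sprintf("  %d users, %d cycle images\n", x$config$n_users, x$n_images))
  for (s in names(x$sides))
    cat(sprintf("  side %s: mean CV accuracy %s over %d runs\n", s,
                x$sides[[s]]$aggregate$overall$formatted,
                length(x$sides[[s]]$confusions)))
  invisible(x)
}
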