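test_that("nearest-neighbor resize follows the stated index map", {
  m <- matrix(c(1, 2), nrow = 1)  # columns c1, c2
  expect_equal(resize_cycle(m, 4), matrix(c(1, 1, 2, 2), nrow = 1))
  m2 <- matrix(rnorm(5 * 16000), nrow = 5)
  expect_identical(resize_cycle(m2, 16000), m2)
  const <- matrix(3, nrow = 2, ncol = 7)
  expect_true(all(resize_cycle(const, 16000) == 3))
  expect_equal(dim(resize_cycle(const, 16000)), c(2L, 16000L))
  expect_error(resize_cycle(matrix(nrow = 2, ncol = 0)), "zero-width")
})

test_that("spectrum segmentation slices exactly at cycle boundaries", {
  spec <- structure(list(magnitude = matrix(seq_len(30), nrow = 3),
                         freqs = c(8, 4, 2), fs = 10),
                    class = "carotid_cwt")
  cyc <- data.frame(start_sample = c(1, 5), end_sample = c(4, 10))
  segs <- segment_spectrum(spec, cyc)
  expect_length(segs, 2)
  expect_equal(ncol(segs[[1]]), 4)
  expect_equal(ncol(segs[[2]]), 6)
  expect_equal(sum(vapply(segs, ncol, 0L)), 10)
  expect_equal(segs[[1]], spec$magnitude[, 1:4])
  expect_length(segment_spectrum(spec, cyc[0, ]), 0)
  bad <- data.frame(start_sample = 8, end_sample = 12)
  expect_error(segment_spectrum(spec, bad), "out of")
  # boundaries at a finer audio rate are mapped onto spectrum columns
  cyc16 <- data.frame(start_sample = 1, end_sample = 16)
  segs2 <- segment_spectrum(spec, cyc16, cycles_fs = 20)
  expect_equal(ncol(segs2[[1]]), 8)
})

test_that("averaging is idempotent and linear and validates shapes", {
  a <- matrix(runif(12), 3)
  expect_equal(unclass(average_spectra(list(a, a)))[, ], a,
               ignore_attr = TRUE)
  fp <- average_spectra(list(a, 3 * a))
  expect_equal(unclass(fp)[, ], 2 * a, ignore_attr = TRUE)
  expect_equal(attr(fp, "n_cycles"), 2)
  expect_error(average_spectra(list()), "empty")
  expect_error(average_spectra(list(a, matrix(0, 2, 4))), "mismatch")
})

test_that("rendered images are fixed-size, bounded and amplitude-invariant", {
  m <- matrix(abs(rnorm(77 * 300)), nrow = 77)
  img <- render_cycle_image(m)
  expect_equal(dim(img), c(134, 134, 3))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  expect_identical(img, render_cycle_image(10 * m))
  # constant-magnitude cycle renders as a single color
  cimg <- render_cycle_image(matrix(5, 10, 10))
  for (ch in 1:3) expect_length(unique(as.vector(cimg[, , ch])), 1)
  # all-zero cycle renders as the colormap's zero color
  zimg <- render_cycle_image(matrix(0, 10, 10))
  lut <- default_colormap()
  expect_true(all(zimg[, , 1] == lut[1, 1] & zimg[, , 2] == lut[1, 2] &
                  zimg[, , 3] == lut[1, 3]))
})

# per-recording fingerprints using ground-truth cycles (bypassing the HSMM
# to isolate the fingerprinting stage)
truth_fingerprint <- function(rec, analysis_fs = 2000, target_len = 2000) {
  cyc <- extract_cycles(truth_frame_states(rec), fs = rec$fs / 50)
  xd <- carotidprint:::resample_audio(rec$samples, rec$fs, analysis_fs)
  spec <- compute_cwt(xd, fs = analysis_fs)
  recording_fingerprint(spec, cyc, cycles_fs = rec$fs,
                        target_len = target_len)
}

test_that("fingerprints are user-specific: intra-user beats inter-user", {
  profiles <- fix_profiles()
  fps <- list()
  for (u in c(1, 4, 7)) {
    for (j in 1:2) {
      rec <- simulate_recording(profiles[[u]], seed = 800 + u * 10 + j)
      fps[[paste0("u", u, "_", j)]] <- as.vector(truth_fingerprint(rec))
    }
  }
  cors <- function(a, b) cor(fps[[a]], fps[[b]])
  intra <- c(cors("u1_1", "u1_2"), cors("u4_1", "u4_2"), cors("u7_1", "u7_2"))
  inter <- c(cors("u1_1", "u4_1"), cors("u1_1", "u7_1"), cors("u4_1", "u7_1"),
             cors("u1_2", "u4_2"), cors("u4_2", "u7_1"))
  expect_gt(min(intra), max(inter))
})

test_that("left and right fingerprints of one user agree closely", {
  p <- fix_profiles()[[3]]
  fl <- lapply(1:2, function(j) as.vector(truth_fingerprint(
    simulate_recording(p, seed = 900 + j, side = "L"))))
  fr <- lapply(1:2, function(j) as.vector(truth_fingerprint(
    simulate_recording(p, seed = 950 + j, side = "R"))))
  fpl <- rowMeans(do.call(cbind, fl))
  fpr <- rowMeans(do.call(cbind, fr))
  expect_gt(cor(fpl, fpr), 0.9)
})
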