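test_that("profiles are deterministic, valid and band-limited", {
  p1 <- make_profiles(7, seed = 1, separation = 0.8)
  p2 <- make_profiles(7, seed = 1, separation = 0.8)
  expect_identical(p1, p2)
  p42a <- make_profiles(3, seed = 42)
  p42b <- make_profiles(3, seed = 42)
  expect_identical(p42a, p42b)
  bands <- sapply(p1, function(p) p$murmur_band)
  expect_true(all(bands >= 4 - 1e-6 & bands <= 100 + 1e-6))
  centers <- sqrt(bands[1, ] * bands[2, ])
  # centers strictly ordered with near-uniform log spacing
  expect_true(all(diff(log2(centers)) > 0.5))
  expect_error(make_profiles(1), "n_users")
  # degenerate separation still yields valid profiles
  p0 <- make_profiles(2, seed = 1, separation = 0)
  expect_length(p0, 2)
})

test_that("simulated recordings honor length, normalization and cyclic truth", {
  p <- fix_profiles()
  rec <- fix_clean_rec()
  expect_equal(length(rec$samples), 11 * 16000)
  expect_equal(max(abs(rec$samples)), 1)
  expect_gte(min(rec$samples), -1)
  # identical seed reproduces exactly
  rec2 <- simulate_recording(p[[1]], seed = 42)
  expect_identical(rec$samples, rec2$samples)
  # states cycle S1 -> systole -> S2 -> diastole with no skips
  r <- rle(as.character(rec$truth_states$state))$values
  nxt <- c(S1 = "systole", systole = "S2", S2 = "diastole", diastole = "S1")
  for (i in seq_len(length(r) - 1)) expect_identical(r[i + 1], nxt[[r[i]]])
  expect_error(simulate_recording(p[[1]], duration = 1), "too short")
  expect_error(simulate_recording(p[[1]], fs = -1), "positive")
})

test_that("S1 burst count tracks the configured heart rate", {
  p60 <- profile_with_hr(60)
  rec <- simulate_recording(p60, duration = 11, seed = 5)
  n_s1 <- sum(rle(as.character(rec$truth_states$state))$values == "S1")
  expect_gte(n_s1, 9)
  expect_lte(n_s1, 13)
})

test_that("murmur energy peaks inside the profile's band", {
  p <- fix_profiles()
  for (u in c(2, 5, 7)) {
    rec <- simulate_recording(p[[u]], seed = 100 + u)
    n <- length(rec$samples)
    half <- seq_len(n %/% 2)
    P <- Mod(fft(rec$samples))[half]^2
    f <- (half - 1) * rec$fs / n
    df <- rec$fs / n
    band <- p[[u]]$murmur_band
    keep <- which(f > 0.5)  # ignore DC/drift bins
    pk <- f[keep[which.max(P[keep])]]
    expect_gte(pk, band[1] - df)
    expect_lte(pk, band[2] + df)
  }
})

test_that("well-separated profiles are separable by murmur-band centroid", {
  p <- make_profiles(2, seed = 7, separation = 1)
  a <- sapply(1:5, function(i)
    band_centroid(simulate_recording(p[[1]], duration = 6, seed = i)))
  b <- sapply(1:5, function(i)
    band_centroid(simulate_recording(p[[2]], duration = 6, seed = 100 + i)))
  expect_true(threshold_separable(a, b))
})

test_that("simulated datasets conserve counts and reproduce bytes", {
  p <- make_profiles(2, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_dataset(p, per_user = 3, sides = "L", out_dir = d1,
                         seed = 9, duration = 3)
  m2 <- simulate_dataset(p, per_user = 3, sides = "L", out_dir = d2,
                         seed = 9, duration = 3)
  expect_equal(nrow(m1), 6)
  expect_true(all(file.exists(m1$path)))
  expect_identical(m1$user, rep(c("U1", "U2"), each = 3))
  # same seed: identical audio bytes
  for (i in seq_len(nrow(m1)))
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
  expect_identical(read.csv(file.path(d1, "manifest.csv"))$quality,
                   read.csv(file.path(d2, "manifest.csv"))$quality)
})

test_that("low-quality flagging matches the calibrated 9/890 rate", {
  flags <- carotidprint:::assign_quality_flags(890, 9 / 890, seed = 1)
  expect_length(flags, 890)
  expect_gte(sum(flags), 2)
  expect_lte(sum(flags), 17)
  expect_identical(flags, carotidprint:::assign_quality_flags(890, 9 / 890,
                                                              seed = 1))
})
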