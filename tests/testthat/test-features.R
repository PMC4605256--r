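test_that("spectral features locate and describe the dominant peak", {
  fs <- 100; t <- (seq_len(60 * fs) - 1) / fs
  set.seed(41)
  x <- sin(2 * pi * 2 * t) + rnorm(length(t), sd = 0.01)
  sp <- spectral_features(x, fs)
  expect_equal(unname(sp["domfreq"]), 2, tolerance = 0.02)
  df <- fs / 2 / (1024 %/% 2)   # spectral bin width
  expect_lte(unname(sp["width"]), 2.5 * df)
  expect_equal(unname(sp["slope"]), unname(sp["amplitude"] / sp["width"]))

  two <- sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 2 * t)
  expect_equal(unname(spectral_features(two, fs)["domfreq"]), 2, tolerance = 0.02)

  wn <- rnorm(length(t))
  spw <- spectral_features(wn, fs)
  expect_lt(unname(spw["amplitude"]), 0.05)   # no concentrated peak
})

test_that("regularity and symmetry behave on constructed waveforms", {
  fs <- 100
  st <- make_steps(seq(1, 50 * 100, by = 50), fs)
  phi <- 2 * pi * (seq_len(5000) - 1) / 50    # one cycle per step

  # identical left/right steps: step-periodic signal
  x <- sin(phi)
  r <- regularity_symmetry(x, st, fs)
  expect_equal(unname(r["step_regularity"]), 1, tolerance = 0.01)
  expect_equal(unname(r["stride_regularity"]), 1, tolerance = 0.01)
  expect_equal(unname(r["step_symmetry"]), 1, tolerance = 0.02)

  # alternating step amplitudes: stride-periodic, asymmetric steps
  amp <- rep(rep(c(1, 0.6), each = 50), 50)
  xa <- amp * sin(phi)
  ra <- regularity_symmetry(xa, st, fs)
  expect_lt(unname(ra["step_regularity"]), unname(ra["stride_regularity"]))
  expect_lt(unname(ra["step_symmetry"]), 1)

  set.seed(42)
  rw <- regularity_symmetry(rnorm(5000), st, fs)
  expect_lt(abs(unname(rw["step_regularity"])), 0.1)
  expect_lt(abs(unname(rw["stride_regularity"])), 0.1)
  expect_true(is.na(regularity_symmetry(rep(2, 5000), st, fs)[["step_regularity"]]))
})

test_that("harmonic ratio follows the even/odd stride-harmonic definition", {
  fs <- 100
  st <- make_steps(seq(1, 50 * 100, by = 50), fs)  # step 0.5 s, stride 1 s
  t <- (seq_len(5000) - 1) / fs
  # stride frequency 1 Hz (odd harmonic), step frequency 2 Hz (even)
  x <- 2 * sin(2 * pi * 2 * t) + 1 * sin(2 * pi * 1 * t)
  expect_equal(harmonic_ratio(x, st, fs, "V"), 2, tolerance = 0.02)
  expect_equal(harmonic_ratio(x, st, fs, "AP"), 2, tolerance = 0.02)
  expect_equal(harmonic_ratio(x, st, fs, "ML"), 0.5, tolerance = 0.02)
  # even harmonics only: capped
  xe <- sin(2 * pi * 2 * t)
  expect_equal(harmonic_ratio(xe, st, fs, "V"), 10)

  # oracle: direct DFT amplitudes at the harmonic bins
  set.seed(43)
  xg <- 2 * sin(2 * pi * 2 * t + 0.3) + 0.8 * sin(2 * pi * 1 * t) +
    0.3 * sin(2 * pi * 3 * t + 1) + rnorm(5000, sd = 0.05)
  amp_k <- function(k) Mod(sum(xg * exp(-2i * pi * k * 1 * t))) * 2 / length(xg)
  amps <- vapply(1:20, amp_k, numeric(1))
  hr_oracle <- sum(amps[seq(2, 20, 2)]) / sum(amps[seq(1, 19, 2)])
  expect_equal(harmonic_ratio(xg, st, fs, "V"), hr_oracle, tolerance = 0.02)
})

test_that("amplitude and timing features use the standard definitions", {
  fs <- 100
  t <- (seq_len(30 * fs) - 1) / fs
  x <- sin(2 * pi * 2 * t)
  expect_equal(sqrt(mean((x - mean(x))^2)), 0.7071, tolerance = 1e-3)
  expect_equal(max(x) - min(x), 2, tolerance = 1e-2)

  st1 <- make_steps(seq(1, 60 * fs, by = 50), fs)
  st2 <- make_steps(seq(1, 90 * fs, by = 50), fs)
  tf <- timing_features(c(60, 90), list(st1, st2), 3600 * fs, fs)
  expect_equal(unname(tf["median_bout_duration"]), 75)
  expect_equal(unname(tf["pct_walking"]), 100 * 150 / 3600, tolerance = 1e-6)
  expect_equal(unname(tf["cadence"]), 120, tolerance = 2)
  expect_equal(unname(tf["average_step_duration"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(tf["average_stride_duration"]), 1.0, tolerance = 1e-6)
  expect_equal(unname(tf["total_bouts"]), 2)
})

test_that("predictor matrices partition the 46 features", {
  fn <- feature_names()
  expect_length(fn, 46)
  set.seed(44)
  df <- as.data.frame(matrix(rnorm(12 * 46), 12, 46))
  names(df) <- fn
  df$subject_id <- sprintf("S%02d", 1:12)
  m <- assemble_matrices(df)
  expect_equal(dim(m$X1), c(12, 46))
  expect_equal(dim(m$X2), c(12, 38))
  expect_equal(dim(m$X3), c(12, 8))
  expect_setequal(c(colnames(m$X2), colnames(m$X3)), colnames(m$X1))
  expect_length(intersect(colnames(m$X2), colnames(m$X3)), 0)
  expect_true(all(abs(colMeans(m$X1)) < 1e-12))
  expect_true(all(abs(apply(m$X1, 2, sd) - 1) < 1e-12))

  # imputation and subject dropping
  df2 <- df
  df2[1, 2] <- NA                      # one missing cell: imputed
  df2[2, 2:40] <- NA                   # > 30% missing: dropped
  expect_warning(m2 <- assemble_matrices(df2), "dropped")
  expect_equal(nrow(m2$X1), 11)
  expect_true(m2$imputed[1, 2])
})
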