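test_that("wavelet detrend separates a sine from a slow trend", {
  fs <- 100
  t <- (seq_len(60 * fs) - 1) / fs
  sine <- sin(2 * pi * 2 * t)
  trend <- 0.2 * t
  x <- sine + trend
  d <- wavelet_detrend(x, fs, stride_period = 1)
  expect_gt(cor(as.numeric(d), sine), 0.99)
  # residual trend in the output: below 1% of the trend's input range
  expect_lt(mean(abs(as.numeric(d) - sine)), 0.01 * diff(range(trend)))
})

test_that("detrending is an exact orthogonal projection", {
  fs <- 100
  set.seed(8)
  x <- cumsum(rnorm(57 * fs)) / 10 + sin(2 * pi * 2 * seq_len(57 * fs) / fs)
  d <- wavelet_detrend(x, fs, stride_period = 1)
  tr <- attr(d, "trend")
  # perfect reconstruction
  expect_lt(max(abs((as.numeric(d) + tr) - x)) / max(abs(x)), 1e-9)
  # orthogonality of the two parts
  expect_lt(abs(sum(as.numeric(d) * tr)) / (sd(x)^2 * length(x)), 1e-9)
  # idempotence
  d2 <- wavelet_detrend(as.numeric(d), fs, stride_period = 1)
  expect_lt(max(abs(as.numeric(d2) - as.numeric(d))) / max(abs(x)), 1e-6)
  # zero in, zero out
  z <- wavelet_detrend(rep(0, 6000), fs, stride_period = 1)
  expect_equal(as.numeric(z), rep(0, 6000))
  # too-short input is a data error
  expect_error(wavelet_detrend(rnorm(100), fs, stride_period = 1),
               class = "gaitlds_data_error")
})

test_that("integration recovers the closed-form antiderivative", {
  fs <- 100; f <- 2
  t <- (seq_len(60 * fs) - 1) / fs
  a <- cos(2 * pi * f * t)
  v <- integrate_to_velocity(a, fs, stride_period = 1)
  ref <- sin(2 * pi * f * t) / (2 * pi * f)
  core <- seq(2 * fs, length(t) - 2 * fs)   # exclude edges
  rel_rms <- sqrt(mean((v[core] - ref[core])^2)) / sqrt(mean(ref[core]^2))
  expect_lt(rel_rms, 0.02)
  expect_equal(as.numeric(integrate_to_velocity(rep(0, 6000), fs, 1)),
               rep(0, 6000))
})

test_that("velocity drift after detrending is negligible on synthetic gait", {
  cfg <- test_cohort_config()
  sim <- simulate_subject(cfg, "S1", "nonfaller")
  b <- detect_walking_bouts(sim$recording)
  prep <- preprocess_bout(bout_acc(sim$recording, b[1, ]), 100)
  n <- nrow(prep$vel)
  t <- seq_len(n) / 100
  for (j in 1:3) {
    slope <- abs(coef(lm(prep$vel[, j] ~ t))[2])   # m/s per s
    expect_lt(slope * 2 * prep$steps$mean_step_time, 1e-3)  # per stride
  }
})

test_that("step detection finds sinusoid maxima and rejects flat input", {
  fs <- 100
  t <- (seq_len(60 * fs) - 1) / fs
  vv <- sin(2 * pi * 2 * t)
  st <- detect_steps(vv, fs)
  expect_equal(length(st$onsets), 120, tolerance = 1)
  expect_equal(st$mean_step_time, 0.5, tolerance = 1e-3)
  expect_equal(length(st$stride_times), length(st$onsets) - 2)
  expect_error(detect_steps(rep(1, 6000), fs), class = "gaitlds_bout_rejected")
  expect_error(detect_steps(sin(2 * pi * 2 * (1:300) / fs), fs, min_steps = 10),
               class = "gaitlds_bout_rejected")
})

test_that("detected steps match the generator ground truth", {
  cfg <- gait_sim_config(n_subjects_per_group = c(faller = 2, nonfaller = 2),
                         bouts_per_subject = 1, bout_duration = 60, seed = 9)
  sim <- simulate_subject(cfg, "S1", "faller")
  gt <- sim$ground_truth
  fs <- 100
  acc <- sim$recording$acc[(gt$bout_start[1] + 1):gt$bout_end[1], ]
  prep <- preprocess_bout(acc, fs)
  true_on <- gt$step_onsets[[1]] - gt$bout_start[1] / fs   # s, relative to bout
  det <- prep$steps$times
  expect_lte(abs(length(det) - length(true_on)), 1)
  # alignment up to the constant template-to-peak offset
  m <- min(length(det), length(true_on))
  err <- det[seq_len(m)] - true_on[seq_len(m)]
  err <- err - median(err)
  expect_lt(sqrt(mean(err^2)), 0.030)
})

test_that("mean step time agrees with the autocorrelation oracle within 5%", {
  cfg <- test_cohort_config()
  sim <- simulate_subject(cfg, "S2", "nonfaller")
  b <- detect_walking_bouts(sim$recording)
  prep <- preprocess_bout(bout_acc(sim$recording, b[1, ]), 100)
  oracle <- acf_period(prep$vel[, 3], 100)
  expect_lt(abs(prep$steps$mean_step_time - oracle) / oracle, 0.05)
})
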