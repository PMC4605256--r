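test_that("lambda_eq1 is the closed-form OLS slope", {
  t <- seq(0, 0.1, by = 0.01)
  c1 <- make_curve(t, -2 + 5 * t)
  expect_equal(lambda_eq1(c1), 5, tolerance = 1e-12)
  c2 <- make_curve(t, rep(-1.3, length(t)))
  expect_equal(lambda_eq1(c2), 0, tolerance = 1e-12)
  set.seed(12)
  y <- rnorm(length(t))
  c3 <- make_curve(t, y)
  expect_equal(lambda_eq1(c3), ols_slope(t, y), tolerance = 1e-12)
  # insufficient points
  c4 <- make_curve(c(0, 0.05), c(1, 2))
  expect_true(is.na(lambda_eq1(c4)))
})

test_that("lambda_eq2 is the log distance ratio over a tenth of the cycle", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(lambda_eq2(make_curve(t, rep(log(0.2), length(t)))), 0)
  y <- rep(log(0.1), length(t)); y[11] <- log(0.1 * exp(1))
  expect_equal(lambda_eq2(make_curve(t, y)), 10, tolerance = 1e-9)
  # exact exponential: eq1 and eq2 agree
  lam <- -3.7
  ye <- log(0.05) + lam * t
  expect_equal(lambda_eq1(make_curve(t, ye)), lambda_eq2(make_curve(t, ye)),
               tolerance = 1e-9)
})

test_that("subject_lambda is a median robust to missing bouts", {
  expect_equal(subject_lambda(c(1, 2, 100)), 2)
  expect_equal(subject_lambda(3.2), 3.2)
  expect_equal(subject_lambda(c(NA, 4, NA, 6)), 5)
  expect_true(is.na(subject_lambda(c(NA_real_, NA_real_))))
})

test_that("mean initial reaction distance matches the exhaustive oracle", {
  cfg <- gait_sim_config(n_subjects_per_group = c(faller = 2, nonfaller = 2),
                         bouts_per_subject = 1, seed = 31)
  sim <- simulate_subject(cfg, "S1", "faller")
  b <- detect_walking_bouts(sim$recording)
  prep <- preprocess_bout(bout_acc(sim$recording, b[1, ]), 100)
  # a ~20-stride toy bout: truncate the trajectory after 21 onsets
  on <- prep$steps$onsets
  keep <- seq_len(on[22] + 5)
  acc <- prep$acc[keep, ]; vel <- prep$vel[keep, ]
  st <- make_steps(on[1:22], 100)
  traj <- embed_differential(acc, vel, st)
  radius <- 0.2 * sqrt(sum(apply(traj$points, 2, var)))
  rc <- reaction_curve(traj, st, 0, radius = radius, min_neighbors = 5)
  oracle <- d0_oracle(traj$points, traj$phase, traj$step, st, 0,
                      radius = radius, phase_tol = 0.05, theiler = 1,
                      min_neighbors = 5)
  expect_equal(exp(rc$log_d[1]), oracle, tolerance = 1e-10)
})

test_that("exclusion rules drop under 10% of strides at default settings", {
  # participant-level: averaged over bouts and phases, as reported per
  # subject by the pipeline
  cfg <- gait_sim_config(n_subjects_per_group = c(faller = 2, nonfaller = 2),
                         bouts_per_subject = 3, bout_duration = 80, seed = 32)
  sim <- simulate_subject(cfg, "S1", "nonfaller")
  b <- detect_walking_bouts(sim$recording)
  fr <- c()
  for (i in seq_len(nrow(b))) {
    prep <- preprocess_bout(bout_acc(sim$recording, b[i, ]), 100)
    traj <- embed_differential(prep$acc, prep$vel, prep$steps)
    for (p in c(0, 0.6)) {
      rc <- reaction_curve(traj, prep$steps, p)
      expect_false(rc$degenerate)
      fr <- c(fr, rc$excluded_fraction)
    }
  }
  expect_lt(mean(fr), 0.10)
})

test_that("a strictly periodic trajectory is flagged degenerate", {
  # identical strides tiled exactly: every same-phase distance is zero
  step <- cbind(sin(2 * pi * (0:49) / 50), cos(2 * pi * (0:49) / 50),
                sin(4 * pi * (0:49) / 50))
  acc <- do.call(rbind, rep(list(step), 30))
  vel <- acc * 0.1
  st <- make_steps(seq(1, 50 * 30, by = 50), 100)
  traj <- embed_differential(acc, vel, st)
  rc <- reaction_curve(traj, st, 0)
  expect_true(rc$degenerate || rc$n_refs == 0)
  expect_true(is.na(lambda_eq1(rc)))
  expect_true(is.na(lambda_eq2(rc)))
})

test_that("lambda is invariant to positive rescaling of the signals", {
  cfg <- test_cohort_config()
  sim <- simulate_subject(cfg, "S1", "faller")
  b <- detect_walking_bouts(sim$recording)
  prep <- preprocess_bout(bout_acc(sim$recording, b[1, ]), 100)
  st <- prep$steps
  t1 <- embed_differential(prep$acc, prep$vel, st)
  t2 <- embed_differential(prep$acc * 3.7, prep$vel * 3.7, st)
  for (p in c(0, 0.6)) {
    r1 <- reaction_curve(t1, st, p); r2 <- reaction_curve(t2, st, p)
    expect_equal(lambda_eq1(r1), lambda_eq1(r2), tolerance = 1e-10)
    expect_equal(lambda_eq2(r1), lambda_eq2(r2), tolerance = 1e-10)
  }
})

test_that("estimated lambda at phase 0 increases with deviation persistence", {
  lam_at <- function(ctr) {
    cfg <- gait_sim_config(
      n_subjects_per_group = c(faller = 2, nonfaller = 2),
      bouts_per_subject = 2, subject_contraction_sd = 0, seed = 33,
      phase_contraction = list(faller = rep(ctr, 5), nonfaller = rep(ctr, 5)))
    vals <- c()
    for (id in c("A", "B")) {
      sim <- simulate_subject(cfg, id, "faller")
      b <- detect_walking_bouts(sim$recording)
      for (i in seq_len(nrow(b))) {
        prep <- preprocess_bout(bout_acc(sim$recording, b[i, ]), 100)
        traj <- embed_differential(prep$acc, prep$vel, prep$steps)
        vals <- c(vals, lambda_eq1(reaction_curve(traj, prep$steps, 0)))
      }
    }
    mean(vals, na.rm = TRUE)
  }
  lams <- vapply(c(-1.2, -0.6, -0.2), lam_at, numeric(1))
  expect_true(all(diff(lams) > 0))
})

test_that("Wolf exponent: neutral on periodic signals, larger on noise", {
  t <- (0:11999) / 100
  x <- sin(2 * pi * t / 0.77)
  w_per <- wolf_lambda(x, 100, theiler = 100)
  expect_lt(abs(w_per), 0.05)
  set.seed(13)
  w_noise <- wolf_lambda(rnorm(12000), 100, theiler = 100)
  expect_gt(w_noise, w_per)
  expect_gt(w_noise, 0)
  expect_true(is.na(wolf_lambda(rnorm(500), 100)))  # too short
})
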