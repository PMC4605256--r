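#' Triaxial trunk-acceleration recording
#'
#' Container for a continuous triaxial (AP/ML/V) dynamic-acceleration record
#' sampled at a fixed rate. Signals are gravity-free (dynamic) acceleration in
#' m/s^2.
#'
#' @param acc numeric matrix with columns `AP`, `ML`, `V` (m/s^2).
#' @param sample_rate sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param group optional group label (`"faller"` / `"nonfaller"`).
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(acc, sample_rate, subject_id = "S1", group = NA_character_) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop_data("acceleration must have 3 channels (AP, ML, V)")
  if (!all(is.finite(acc))) stop_data("non-finite acceleration samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop_config("sample_rate must be > 0")
  colnames(acc) <- c("AP", "ML", "V")
  structure(
    list(acc = acc, sample_rate = sample_rate,
         subject_id = subject_id, group = group),
    class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> subject %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$acc), x$sample_rate,
              nrow(x$acc) / x$sample_rate))
  invisible(x)
}

#' Configuration for the synthetic gait generator
#'
#' The generator emulates multi-bout free-living recordings: walking bouts of
#' quasi-periodic step cycles around 2 steps/s separated by low-amplitude rest,
#' with a per-phase first-order (AR(1)) deviation process whose step-to-step
#' decay `exp(phase_contraction[p])` is the known ground-truth analogue of
#' phase-dependent local dynamic stability.
#'
#' @param sample_rate sampling rate (Hz).
#' @param n_subjects_per_group named vector `c(faller=, nonfaller=)`.
#' @param bouts_per_subject walking bouts per subject; a length-2 vector is a
#'   range sampled uniformly per subject.
#' @param bout_duration bout duration in seconds (>= 60); a length-2 vector
#'   is a range sampled uniformly per bout.
#' @param step_frequency_mean mean step frequency (Hz).
#' @param step_frequency_cv coefficient of variation of step duration.
#' @param phase_contraction list with elements `faller` and `nonfaller`, each a
#'   length-5 numeric vector of per-phase log contraction rates (negative) at
#'   0, 20, 40, 60, 80% of the step cycle.
#' @param subject_contraction_sd between-subject SD of the log contraction.
#' @param subject_amp_sd between-subject SD of the per-axis log template
#'   amplitude.
#' @param subject_freq_sd between-subject coefficient of variation of the
#'   mean step frequency.
#' @param subject_asym_sd between-subject SD of the log left/right asymmetry
#'   scale.
#' @param dynamical_noise_sd stationary SD of the per-phase deviation process
#'   (template units, m/s^2).
#' @param measurement_noise_sd white sensor noise SD (m/s^2), added last.
#' @param rest_gap_duration rest duration between bouts (s).
#' @param seed integer seed; same config + seed gives bit-identical output.
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(sample_rate = 100,
                            n_subjects_per_group = c(faller = 5, nonfaller = 5),
                            bouts_per_subject = c(5, 8),
                            bout_duration = c(60, 75),
                            step_frequency_mean = 2,
                            step_frequency_cv = 0.03,
                            phase_contraction = list(
                              faller    = c(-0.9, -0.9, -0.9, -0.9, -0.9),
                              nonfaller = c(-0.25, -0.9, -0.9, -0.25, -0.9)),
                            subject_contraction_sd = 0.15,
                            subject_amp_sd = 0.12,
                            subject_freq_sd = 0.06,
                            subject_asym_sd = 0.25,
                            dynamical_noise_sd = 0.15,
                            measurement_noise_sd = 0.02,
                            rest_gap_duration = 20,
                            seed = NULL) {
  if (any(bout_duration < 60)) stop_config("bout_duration must be >= 60 s")
  if (sample_rate <= 0) stop_config("sample_rate must be > 0")
  if (step_frequency_mean <= 0) stop_config("step_frequency_mean must be > 0")
  if (any(bouts_per_subject < 1)) stop_config("bouts_per_subject must be >= 1")
  if (rest_gap_duration <= 0) stop_config("rest_gap_duration must be > 0")
  if (dynamical_noise_sd < 0 || measurement_noise_sd < 0)
    stop_config("noise SDs must be >= 0")
  for (g in names(phase_contraction)) {
    pc <- phase_contraction[[g]]
    if (length(pc) != 5L || !all(is.finite(pc)) || any(pc >= 0))
      stop_config("phase_contraction must be 5 finite negative values per group")
  }
  structure(
    list(sample_rate = sample_rate,
         n_subjects_per_group = n_subjects_per_group,
         bouts_per_subject = bouts_per_subject,
         bout_duration = bout_duration,
         step_frequency_mean = step_frequency_mean,
         step_frequency_cv = step_frequency_cv,
         phase_contraction = phase_contraction,
         subject_contraction_sd = subject_contraction_sd,
         subject_amp_sd = subject_amp_sd,
         subject_freq_sd = subject_freq_sd,
         subject_asym_sd = subject_asym_sd,
         dynamical_noise_sd = dynamical_noise_sd,
         measurement_noise_sd = measurement_noise_sd,
         rest_gap_duration = rest_gap_duration,
         rest_noise_sd = 0.015,
         seed = seed),
    class = "gait_sim_config")
}

# Deterministic per-subject seed. The cohort seed and the id hash are mixed
# multiplicatively (Lehmer-style) so that neighbouring cohort seeds map to
# distant subject seeds: naive `seed + hash` makes nearby cohort seeds give
# correlated early draws for every subject, which does not average out across
# replicate cohorts.
subject_seed <- function(seed, subject_id) {
  h <- 0
  for (k in utf8ToInt(as.character(subject_id))) h <- (h * 131 + k) %% 33554432
  s <- (seed %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h * 69621) %% 2147483646 + 1)
}

# Step-template waveforms (m/s^2) as functions of step phase phi in [0,1) and
# step parity s = +/-1. V is dominated by the step frequency, ML by the stride
# frequency (sign alternates with parity), AP carries both plus a small
# left/right asymmetry, so harmonic-ratio features behave directionally as in
# real gait. `amp` scales the three axes and `asym` the parity (left/right)
# components, giving between-subject heterogeneity.
template_acc <- function(phi, parity, amp = c(1, 1, 1), asym = 1) {
  ap <- amp[1] * (1.2 * sin(2 * pi * phi + 0.8) + 0.4 * sin(4 * pi * phi) +
                    0.25 * asym * parity * sin(pi * phi))
  ml <- amp[2] * (0.7 * asym * parity * sin(pi * phi) +
                    0.15 * sin(4 * pi * phi))
  v  <- amp[3] * (-2.0 * sin(2 * pi * phi) + 0.4 * sin(4 * pi * phi))
  cbind(AP = ap, ML = ml, V = v)
}

# per-axis weight of the deviation process, the acceleration amplitude
# (m/s^2) of a unit deviation, and the velocity amplitude (m/s) of a unit
# deviation
# V gets a small deviation weight: step onsets are detected as vertical
# velocity maxima, and perturbing V strongly would jitter the detected
# reference points themselves
DEV_WEIGHT <- c(AP = 1.0, ML = 0.7, V = 0.15)
DEV_AACC <- 1.2
DEV_VREF <- 0.08

# Render one walking bout. Returns acc matrix, step onset times (s, relative
# to bout start), and the per-step deviation matrix (n_steps x 5).
simulate_bout <- function(config, log_a, duration, f0 = NULL,
                          amp = c(1, 1, 1), asym = 1) {
  fs <- config$sample_rate
  if (is.null(f0)) f0 <- config$step_frequency_mean
  cv <- config$step_frequency_cv

  # step durations: generate until the bout duration is reached
  durs <- numeric(0)
  total <- 0
  while (total < duration) {
    z <- if (cv > 0) max(-3, min(3, rnorm(1))) else 0
    d <- max(0.25 / f0, (1 / f0) * (1 + cv * z))
    durs <- c(durs, d)
    total <- total + d
  }
  n_steps <- length(durs)
  onsets <- c(0, cumsum(durs))           # n_steps + 1 boundaries

  # per-phase AR(1) deviation series across steps (stationary SD sigma_d)
  sigma_d <- config$dynamical_noise_sd
  a <- exp(log_a)                         # length 5
  dev <- matrix(0, n_steps, 5)
  if (sigma_d > 0) {
    for (m in 1:5) {
      innov_sd <- sigma_d * sqrt(1 - a[m]^2)
      d_m <- numeric(n_steps)
      d_m[1] <- rnorm(1, sd = sigma_d)
      if (n_steps > 1) {
        eps <- rnorm(n_steps - 1, sd = innov_sd)
        for (k in 2:n_steps) d_m[k] <- a[m] * d_m[k - 1] + eps[k - 1]
      }
      dev[, m] <- d_m
    }
  }

  n <- floor(total * fs)
  t <- (seq_len(n) - 1) / fs
  k <- findInterval(t, onsets, rightmost.closed = FALSE)  # step index 1..n_steps
  k[k > n_steps] <- n_steps
  phi <- (t - onsets[k]) / durs[k]
  phi <- pmin(pmax(phi, 0), 1 - 1e-9)
  parity <- ifelse(k %% 2 == 0, 1, -1)

  acc <- template_acc(phi, parity, amp = amp, asym = asym)

  # Deviation rendering, two components per 20%-of-step segment [p, p+0.2):
  #
  # (1) Velocity: a continuous perturbation that EQUALS the AR(1) value
  #     d_k(p) at each phase checkpoint p and decays geometrically at the
  #     ground-truth rate exp(log_a[p]):
  #       v_dev(frac) = V_REF * [ d_k(p) a_p^frac + (d_next - d_k(p) a_p) s(frac) ]
  #     with s a smoothstep ramp active only in the last 40% of the segment
  #     (outside the first-10%-of-cycle measurement window), carrying the
  #     trajectory to the next checkpoint's value. Its analytic time
  #     derivative is injected into the acceleration so the integrated
  #     velocity carries the contracting deviation.
  #
  # (2) Acceleration: the same decaying envelope on a zero-mean cosine
  #     carrier, A_ACC * d_k(p) a_p^frac cos(4 pi frac), directly visible to
  #     acceleration-based state spaces while integrating to a negligible
  #     velocity footprint.
  m_idx <- pmin(floor(phi / 0.2) + 1, 5)
  frac <- (phi - (m_idx - 1) * 0.2) / 0.2
  a_m <- exp(log_a[m_idx])
  env <- a_m^frac
  # deviation at the next checkpoint (wrapping to the next step's phase 0)
  dnext <- matrix(0, n_steps, 5)
  dnext[, 1:4] <- dev[, 2:5]
  if (n_steps > 1) dnext[1:(n_steps - 1), 5] <- dev[2:n_steps, 1]
  dnext[n_steps, 5] <- dev[n_steps, 5] * exp(log_a[5])  # free end: no ramp
  dm <- dev[cbind(k, m_idx)]
  dn <- dnext[cbind(k, m_idx)]
  u <- pmin(pmax((frac - 0.6) / 0.4, 0), 1)
  s_d <- 6 * u * (1 - u) / 0.4
  dfrac_dt <- 1 / (0.2 * durs[k])
  a_dev <- DEV_VREF * (dm * log(a_m) * env + (dn - dm * a_m) * s_d) * dfrac_dt +
    DEV_AACC * dm * env * cos(4 * pi * frac)
  for (ax in 1:3) acc[, ax] <- acc[, ax] + DEV_WEIGHT[ax] * a_dev

  list(acc = acc, onsets = onsets[seq_len(n_steps)], durations = durs,
       deviations = dev, duration = total)
}

#' Simulate one subject's multi-bout recording
#'
#' @param config a [gait_sim_config()].
#' @param subject_id subject identifier (also seeds the subject's RNG stream).
#' @param group `"faller"` or `"nonfaller"`.
#' @return A list with elements `recording` ([triaxial_recording]) and
#'   `ground_truth` (bout schedule, step onsets, per-step deviations, true
#'   per-phase contraction rates, group label).
#' @export
simulate_subject <- function(config, subject_id, group = c("faller", "nonfaller")) {
  group <- match.arg(group)
  if (!inherits(config, "gait_sim_config")) stop_config("config must be a gait_sim_config")
  if (!is.null(config$seed)) {
    set.seed(subject_seed(config$seed, subject_id))
    invisible(runif(20))   # burn-in: early draws of nearby seeds correlate
  }

  fs <- config$sample_rate
  base <- config$phase_contraction[[group]]
  log_a <- base + rnorm(5, sd = config$subject_contraction_sd)
  log_a <- pmin(log_a, -0.02)            # contraction must stay strictly < 0
  # subject-level gait style: template amplitude, cadence, asymmetry
  amp <- exp(rnorm(3, sd = config$subject_amp_sd))
  f0_subj <- config$step_frequency_mean *
    (1 + max(-2.5, min(2.5, rnorm(1))) * config$subject_freq_sd)
  asym <- exp(rnorm(1, sd = config$subject_asym_sd))

  rest_n <- round(config$rest_gap_duration * fs)
  segs <- list()
  bout_start <- integer(0); bout_end <- integer(0)
  step_times <- list(); deviations <- list(); bout_durs <- numeric(0)

  cursor <- 0L
  add_rest <- function() matrix(rnorm(rest_n * 3, sd = config$rest_noise_sd), rest_n, 3)

  n_bouts <- if (length(config$bouts_per_subject) == 2)
    sample(seq(config$bouts_per_subject[1], config$bouts_per_subject[2]), 1)
  else config$bouts_per_subject

  segs[[length(segs) + 1]] <- add_rest(); cursor <- cursor + rest_n
  for (b in seq_len(n_bouts)) {
    dur <- if (length(config$bout_duration) == 2)
      runif(1, config$bout_duration[1], config$bout_duration[2])
    else config$bout_duration
    bout <- simulate_bout(config, log_a, dur, f0 = f0_subj, amp = amp,
                          asym = asym)
    nb <- nrow(bout$acc)
    bout_start <- c(bout_start, cursor)                     # 0-based half-open
    bout_end <- c(bout_end, cursor + nb)
    step_times[[b]] <- bout$onsets + cursor / fs
    deviations[[b]] <- bout$deviations
    bout_durs <- c(bout_durs, bout$duration)
    segs[[length(segs) + 1]] <- bout$acc; cursor <- cursor + nb
    segs[[length(segs) + 1]] <- add_rest(); cursor <- cursor + rest_n
  }
  acc <- do.call(rbind, segs)
  if (config$measurement_noise_sd > 0) {
    acc <- acc + matrix(rnorm(length(acc), sd = config$measurement_noise_sd),
                        nrow(acc), 3)
  }
  rec <- triaxial_recording(acc, fs, subject_id = subject_id, group = group)
  gt <- list(subject_id = subject_id, group = group,
             bout_start = bout_start, bout_end = bout_end,
             bout_duration = bout_durs,
             step_onsets = step_times,
             deviations = deviations,
             contraction = log_a,
             phases = LDS_PHASES)
  list(recording = rec, ground_truth = gt)
}

#' Simulate a cohort of fallers and nonfallers
#'
#' @param config a [gait_sim_config()]; `n_subjects_per_group` controls the
#'   (possibly unbalanced) group sizes.
#' @return A list with `recordings` (list of [triaxial_recording]), `manifest`
#'   (data.frame: subject_id, group) and `ground_truth` (named list).
#' @export
simulate_cohort <- function(config) {
  n <- config$n_subjects_per_group
  if (any(n < 2)) stop_config("need >= 2 subjects per group")
  ids <- c(sprintf("F%02d", seq_len(n[["faller"]])),
           sprintf("N%02d", seq_len(n[["nonfaller"]])))
  groups <- c(rep("faller", n[["faller"]]), rep("nonfaller", n[["nonfaller"]]))
  recordings <- vector("list", length(ids))
  gts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sim <- simulate_subject(config, ids[i], groups[i])
    recordings[[i]] <- sim$recording
    gts[[i]] <- sim$ground_truth
  }
  names(recordings) <- ids
  names(gts) <- ids
  list(recordings = recordings,
       manifest = data.frame(subject_id = ids, group = groups,
                             stringsAsFactors = FALSE),
       ground_truth = gts)
}

#' Read and write columnar recordings
#'
#' Recordings are interchanged as plain columnar text with a header line
#' `time_s  acc_AP  acc_ML  acc_V` (tab-separated).
#'
#' @param rec a [triaxial_recording].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [triaxial_recording].
#' @export
write_recording <- function(rec, path) {
  t <- (seq_len(nrow(rec$acc)) - 1) / rec$sample_rate
  df <- data.frame(time_s = t, acc_AP = rec$acc[, 1], acc_ML = rec$acc[, 2],
                   acc_V = rec$acc[, 3])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param subject_id,group metadata attached to the recording on read.
#' @export
read_recording <- function(path, subject_id = basename(path), group = NA_character_) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- read.table(path, header = has_header, sep = "", comment.char = "#")
  if (ncol(df) < 4) stop_data("expected 4 columns: time + AP/ML/V acceleration")
  dt <- median(diff(df[[1]]))
  triaxial_recording(as.matrix(df[, 2:4]), sample_rate = 1 / dt,
                     subject_id = subject_id, group = group)
}

#' Write a simulated cohort to disk
#'
#' Writes one columnar time-series file per subject, a `manifest.csv`
#' (subject_id, group, file) and a JSON ground-truth sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return The manifest data.frame (with file paths) invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$subject_id[i]
    files[i] <- file.path(dir, paste0(id, ".tsv"))
    write_recording(cohort$recordings[[id]], files[i])
  }
  manifest <- cbind(cohort$manifest, file = basename(files))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
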