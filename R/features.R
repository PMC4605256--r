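AXES <- c("AP", "ML", "V")

# the eight phase-dependent stability features used in the discriminant set
PHASE_LAMBDA_FEATURES <- as.vector(outer(
  c("lambda_diff", "lambda_lag"),
  c("p0_eq1", "p0_eq2", "p60_eq1", "p60_eq2"),
  paste, sep = "_"))

PER_AXIS_FEATURES <- c("wolf", "acc_rms", "acc_range", "harmonic_ratio",
                       "step_symmetry", "step_regularity", "stride_regularity",
                       "domfreq_amplitude", "domfreq_width", "domfreq_slope")

SCALAR_FEATURES <- c("cadence", "average_step_duration",
                     "average_stride_duration", "median_bout_duration",
                     "median_steps_per_bout", "total_steps", "total_bouts",
                     "pct_walking")

#' Canonical gait feature names
#'
#' The 46-feature battery: 8 phase-dependent stability features, 10 per-axis
#' features for each of AP/ML/V, and 8 scalar timing/volume features.
#' @return character vector of length 46.
#' @export
feature_names <- function() {
  c(PHASE_LAMBDA_FEATURES,
    as.vector(t(outer(PER_AXIS_FEATURES, AXES, paste, sep = "_"))),
    SCALAR_FEATURES)
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-removed, 50%-overlapping segment-averaged
#' periodogram.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate (Hz).
#' @param nperseg segment length (samples).
#' @return list with `freq` (Hz) and `power` (relative units).
#' @export
welch_psd <- function(x, sample_rate, nperseg = min(length(x), 1024L)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  nf <- nperseg %/% 2L + 1L
  pw <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2
    pw <- pw + p[seq_len(nf)]
  }
  list(freq = seq(0, sample_rate / 2, length.out = nf),
       power = pw / length(starts))
}

#' Dominant-frequency spectral features
#'
#' Dominant frequency = highest Welch-spectrum peak in the locomotor band;
#' amplitude = peak power as a fraction of total power; width = frequency
#' span around the peak where power stays above half the peak; slope =
#' amplitude / width.
#'
#' @param x bout acceleration axis.
#' @param sample_rate sampling rate (Hz).
#' @param band locomotor band (Hz).
#' @return named vector: domfreq, amplitude, width, slope.
#' @export
spectral_features <- function(x, sample_rate, band = c(0.5, 3)) {
  ps <- welch_psd(x, sample_rate)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  if (length(sel) == 0 || all(ps$power[sel] == 0))
    return(c(domfreq = NA_real_, amplitude = NA_real_, width = NA_real_,
             slope = NA_real_))
  ipk <- sel[which.max(ps$power[sel])]
  peak <- ps$power[ipk]
  total <- sum(ps$power)
  amplitude <- peak / total
  # sub-bin dominant frequency by parabolic interpolation of log power
  domfreq <- ps$freq[ipk]
  if (ipk > 1 && ipk < length(ps$power) &&
      ps$power[ipk - 1] > 0 && ps$power[ipk + 1] > 0) {
    la <- log(ps$power[ipk - 1]); lb <- log(peak); lc <- log(ps$power[ipk + 1])
    den <- la - 2 * lb + lc
    if (den < 0) domfreq <- domfreq +
        0.5 * (la - lc) / den * (ps$freq[2] - ps$freq[1])
  }
  half <- peak / 2
  lo <- ipk
  while (lo > 1 && ps$power[lo - 1] >= half) lo <- lo - 1
  hi <- ipk
  while (hi < length(ps$power) && ps$power[hi + 1] >= half) hi <- hi + 1
  df <- ps$freq[2] - ps$freq[1]
  width <- (hi - lo + 1) * df
  c(domfreq = domfreq, amplitude = amplitude, width = width,
    slope = amplitude / width)
}

# unbiased normalised autocorrelation at an integer lag
acf_at_lag <- function(xc, lag, c0) {
  n <- length(xc)
  if (lag <= 0 || lag >= n) return(NA_real_)
  r <- sum(xc[1:(n - lag)] * xc[(1 + lag):n]) / (n - lag) / c0
  max(-1, min(1, r))
}

#' Step and stride regularity and step symmetry
#'
#' Unbiased normalised autocorrelation of the axis signal evaluated at the
#' mean step-time and mean stride-time lags; step symmetry is the ratio
#' `|step regularity| / |stride regularity|`, replaced by its reciprocal when
#' above 1 so that symmetry always lies in `[0, 1]`.
#'
#' @param x bout acceleration axis.
#' @param steps the bout `step_series`.
#' @param sample_rate sampling rate (Hz).
#' @return named vector: step_regularity, stride_regularity, step_symmetry.
#' @export
regularity_symmetry <- function(x, steps, sample_rate) {
  if (sd(x) == 0)
    return(c(step_regularity = NA_real_, stride_regularity = NA_real_,
             step_symmetry = NA_real_))
  xc <- x - mean(x)
  c0 <- sum(xc^2) / length(xc)
  step_lag <- as.integer(round(steps$mean_step_time * sample_rate))
  stride_lag <- as.integer(round(mean(steps$stride_times) * sample_rate))
  sr <- acf_at_lag(xc, step_lag, c0)
  strr <- acf_at_lag(xc, stride_lag, c0)
  sym <- if (is.finite(sr) && is.finite(strr) && abs(strr) > 0) {
    v <- abs(sr) / abs(strr)
    if (v > 1) 1 / v else v
  } else NA_real_
  c(step_regularity = sr, stride_regularity = strr, step_symmetry = sym)
}

#' Harmonic ratio of a bout acceleration axis
#'
#' Finite-Fourier amplitudes at the first `n_harmonics` harmonics of the
#' stride frequency. AP and V: ratio of even-harmonic to odd-harmonic
#' amplitude sums (step-frequency content is an even stride harmonic); ML:
#' odd over even.
#'
#' @param x bout acceleration axis.
#' @param steps the bout `step_series`.
#' @param sample_rate sampling rate (Hz).
#' @param axis `"AP"`, `"ML"` or `"V"`.
#' @param n_harmonics number of stride harmonics.
#' @param cap upper cap for degenerate denominators.
#' @return harmonic ratio (scalar).
#' @export
harmonic_ratio <- function(x, steps, sample_rate, axis = c("AP", "ML", "V"),
                           n_harmonics = 20, cap = 10) {
  axis <- match.arg(axis)
  stride_t <- mean(steps$stride_times)
  if (!is.finite(stride_t) || stride_t <= 0) return(NA_real_)
  f0 <- 1 / stride_t
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  xc <- x - mean(x)
  amp <- vapply(seq_len(n_harmonics), function(k) {
    Mod(sum(xc * exp(-2i * pi * k * f0 * t))) * 2 / n
  }, numeric(1))
  even <- sum(amp[seq(2, n_harmonics, by = 2)])
  odd <- sum(amp[seq(1, n_harmonics, by = 2)])
  hr <- if (axis == "ML") odd / max(even, .Machine$double.eps) else
    even / max(odd, .Machine$double.eps)
  min(hr, cap)
}

#' Per-axis gait features for one bout
#'
#' @param acc detrended bout acceleration (n x 3, AP/ML/V).
#' @param steps the bout `step_series`.
#' @param sample_rate sampling rate (Hz).
#' @return named numeric vector (27 entries: 9 features x 3 axes, Wolf
#'   excluded).
#' @export
bout_gait_features <- function(acc, steps, sample_rate) {
  out <- c()
  for (j in seq_along(AXES)) {
    x <- acc[, j]
    ax <- AXES[j]
    xc <- x - mean(x)
    sp <- spectral_features(x, sample_rate)
    rs <- regularity_symmetry(x, steps, sample_rate)
    v <- c(sqrt(mean(xc^2)), max(x) - min(x),
           harmonic_ratio(x, steps, sample_rate, ax),
           rs[["step_symmetry"]], rs[["step_regularity"]],
           rs[["stride_regularity"]],
           sp[["amplitude"]], sp[["width"]], sp[["slope"]])
    names(v) <- paste(c("acc_rms", "acc_range", "harmonic_ratio",
                        "step_symmetry", "step_regularity",
                        "stride_regularity", "domfreq_amplitude",
                        "domfreq_width", "domfreq_slope"), ax, sep = "_")
    out <- c(out, v)
  }
  out
}

#' Timing and walking-volume features for one subject
#'
#' @param bout_durations per-bout durations (s).
#' @param steps_list list of per-bout `step_series`.
#' @param n_samples total recording length (samples).
#' @param sample_rate sampling rate (Hz).
#' @return named numeric vector of the 8 scalar features.
#' @export
timing_features <- function(bout_durations, steps_list, n_samples, sample_rate) {
  all_step_times <- unlist(lapply(steps_list, `[[`, "step_times"))
  all_stride_times <- unlist(lapply(steps_list, `[[`, "stride_times"))
  steps_per_bout <- vapply(steps_list, function(s) length(s$onsets), numeric(1))
  total_steps <- sum(steps_per_bout)
  walking_s <- sum(bout_durations)
  c(cadence = total_steps / (walking_s / 60),
    average_step_duration = mean(all_step_times),
    average_stride_duration = mean(all_stride_times),
    median_bout_duration = median(bout_durations),
    median_steps_per_bout = median(steps_per_bout),
    total_steps = total_steps,
    total_bouts = length(bout_durations),
    pct_walking = 100 * walking_s * sample_rate / n_samples)
}

#' Assemble the three predictor matrices
#'
#' `X1` holds all 46 features, `X2` drops the 8 phase-dependent stability
#' features, `X3` keeps only those 8. Missing entries are imputed with the
#' cohort median; subjects missing more than `max_missing` of their features
#' are dropped with a warning.
#'
#' @param features data.frame with a `subject_id` column and the 46 feature
#'   columns of [feature_names()].
#' @param scale z-score the columns.
#' @param max_missing maximum tolerated fraction of missing features.
#' @return list with matrices `X1`, `X2`, `X3` (rownames = subject ids) and
#'   `imputed` (logical matrix of imputed cells).
#' @export
assemble_matrices <- function(features, scale = TRUE, max_missing = 0.3) {
  fn <- feature_names()
  missing_cols <- setdiff(fn, names(features))
  if (length(missing_cols) > 0)
    stop_data("missing feature columns: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, fn])
  rownames(X) <- features$subject_id
  frac_missing <- rowMeans(!is.finite(X))
  if (any(frac_missing > max_missing)) {
    warning(sum(frac_missing > max_missing),
            " subject(s) dropped (> ", 100 * max_missing, "% missing features)")
    X <- X[frac_missing <= max_missing, , drop = FALSE]
  }
  imputed <- !is.finite(X)
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- median(X[!bad, j])
  }
  if (scale) X <- scale_columns(X)
  list(X1 = X,
       X2 = X[, setdiff(fn, PHASE_LAMBDA_FEATURES), drop = FALSE],
       X3 = X[, PHASE_LAMBDA_FEATURES, drop = FALSE],
       imputed = imputed)
}
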