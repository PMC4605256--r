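#' Step-phase annotation
#'
#' Fraction of the current step elapsed (in `[0, 1)`) for every sample, plus
#' the step index; `NA` outside the first/last detected onset.
#'
#' @param n number of samples.
#' @param steps a `step_series` from [detect_steps()].
#' @return list with numeric `phase` and integer `step` (both length `n`).
#' @export
step_phase <- function(n, steps) {
  phase <- rep(NA_real_, n)
  stepi <- rep(NA_integer_, n)
  on <- steps$onsets
  for (k in seq_len(length(on) - 1)) {
    idx <- on[k]:(on[k + 1] - 1L)
    phase[idx] <- (idx - on[k]) / (on[k + 1] - on[k])
    stepi[idx] <- k
  }
  list(phase = phase, step = stepi)
}

new_state_trajectory <- function(points, method, lag, phase, step) {
  structure(list(points = points, method = method, lag = lag,
                 phase = phase, step = step),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %s: %d points x %d dims\n",
              x$method, nrow(x$points), ncol(x$points)))
  invisible(x)
}

# z-score columns; constant columns are centred only
scale_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

#' Differential 6D state-space reconstruction
#'
#' State vector `[a_AP, a_ML, a_V, v_AP, v_ML, v_V]`. Acceleration and
#' velocity have incommensurate units, so each column is standardised to unit
#' variance before any distance computation.
#'
#' @param acc detrended bout acceleration (n x 3).
#' @param vel intrastep velocity (n x 3), aligned with `acc`.
#' @param steps optional `step_series` used to annotate each state point with
#'   its step phase.
#' @return A `state_trajectory` (method `"diff"`).
#' @export
embed_differential <- function(acc, vel, steps = NULL) {
  if (nrow(acc) != nrow(vel)) stop_data("acceleration/velocity length mismatch")
  pts <- scale_columns(cbind(acc, vel))
  colnames(pts) <- c("a_AP", "a_ML", "a_V", "v_AP", "v_ML", "v_V")
  ann <- if (!is.null(steps)) step_phase(nrow(pts), steps) else
    list(phase = rep(NA_real_, nrow(pts)), step = rep(NA_integer_, nrow(pts)))
  new_state_trajectory(pts, "diff", NA_integer_, ann$phase, ann$step)
}

#' Delayed 6D state-space reconstruction
#'
#' State vector `[v_AP(t), v_AP(t+l dt), v_ML(t), v_ML(t+l dt), v_V(t),
#' v_V(t+l dt)]`. The short default lag `l = 3` samples avoids blending gait
#' phases within a state point. The point at index `t` is annotated with the
#' phase of sample `t`.
#'
#' @param vel intrastep velocity (n x 3).
#' @param l delay in samples (>= 1).
#' @param steps optional `step_series` for phase annotation.
#' @return A `state_trajectory` (method `"lag"`, `n - l` points).
#' @export
embed_delayed <- function(vel, l = 3, steps = NULL) {
  l <- as.integer(l)
  if (l < 1) stop_data("lag l must be >= 1 (l = 0 duplicates columns)")
  n <- nrow(vel)
  if (l >= n) stop_data("lag l must be smaller than the signal length")
  idx <- seq_len(n - l)
  pts <- cbind(vel[idx, 1], vel[idx + l, 1],
               vel[idx, 2], vel[idx + l, 2],
               vel[idx, 3], vel[idx + l, 3])
  colnames(pts) <- c("v_AP", "v_AP_l", "v_ML", "v_ML_l", "v_V", "v_V_l")
  pts <- scale_columns(pts)
  ann <- if (!is.null(steps)) step_phase(n, steps) else
    list(phase = rep(NA_real_, n), step = rep(NA_integer_, n))
  new_state_trajectory(pts, "lag", l, ann$phase[idx], ann$step[idx])
}

#' First minimum of the average mutual information
#'
#' Mutual information between `x(t)` and `x(t + tau)` estimated with
#' equiprobable binning, for `tau = 1..max_lag`. Returns the first strict
#' interior local minimum; if none exists, the argmin is returned with a
#' warning.
#'
#' @param x numeric signal.
#' @param max_lag largest delay searched (samples).
#' @param bins number of equiprobable bins.
#' @return Integer lag (samples), with the MI profile in attribute `"mi"`.
#' @export
ami_first_minimum <- function(x, max_lag = 25, bins = 16) {
  if (sd(x) == 0) stop_data("mutual information undefined for constant signal")
  n <- length(x)
  if (n < 10 * max_lag) stop_data("signal too short for AMI lag search")
  # equiprobable binning via ranks
  b <- ceiling(rank(x, ties.method = "first") / (n / bins))
  b[b > bins] <- bins
  mi <- numeric(max_lag)
  for (tau in seq_len(max_lag)) {
    joint <- table(b[1:(n - tau)], b[(1 + tau):n]) / (n - tau)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    mi[tau] <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  }
  interior <- which(mi[2:(max_lag - 1)] < mi[1:(max_lag - 2)] &
                    mi[2:(max_lag - 1)] < mi[3:max_lag]) + 1L
  if (length(interior) > 0) {
    lag <- interior[1]
  } else {
    warning("no strict interior AMI minimum; returning argmin")
    lag <- which.min(mi)
  }
  structure(as.integer(lag), mi = mi)
}
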