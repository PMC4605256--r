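#' Perturbation reaction curve at a step-cycle phase
#'
#' For each stride's reference point at phase `p`, neighbours are trajectory
#' points on other strides at the same phase (within `phase_tol`), at least
#' `theiler` strides away in time and within `radius` of the reference.
#' Each neighbour's distance to the reference trajectory is traced forward to
#' the next step onset, normalised to step time, resampled on a common grid
#' of 101 points per step cycle and averaged over neighbours and strides.
#'
#' References with fewer than `min_neighbors` neighbours or with an
#' instantaneous stride time outside the 5-95 stride-time percentiles are
#' excluded; the excluded fraction is recorded.
#'
#' @param traj a `state_trajectory` with step-phase annotation.
#' @param steps the `step_series` of the bout.
#' @param phase initial perturbation phase, one of 0, 0.2, 0.4, 0.6, 0.8.
#' @param radius neighbourhood radius; default 0.3 of the global trajectory
#'   SD (root of the summed column variances), which keeps the neighbourhood
#'   local while yielding at least 10 neighbour strides on 60-s bouts.
#' @param phase_tol phase tolerance for neighbour eligibility (fraction of
#'   the step cycle).
#' @param theiler Theiler exclusion window in strides.
#' @param min_neighbors minimum neighbour count per reference.
#' @param stride_pct stride-time percentile bounds for the exclusion filter.
#' @return A `reaction_curve`: list with `phase`, `t` (step-normalised grid),
#'   `log_d` (mean log reaction distance), `n_refs`, `excluded_fraction`,
#'   `degenerate`.
#' @export
reaction_curve <- function(traj, steps, phase,
                           radius = NULL, phase_tol = 0.05, theiler = 1,
                           min_neighbors = 10, stride_pct = c(0.05, 0.95)) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (!any(abs(phase - LDS_PHASES) < 1e-9))
    stop_config("phase must be one of 0, 0.2, 0.4, 0.6, 0.8")
  pts <- traj$points
  npts <- nrow(pts)
  phi <- traj$phase
  stp <- traj$step
  on <- steps$onsets
  n_steps <- length(on) - 1L
  if (n_steps < 10) reject_bout("fewer than 10 strides in bout")
  if (is.null(radius)) radius <- 0.3 * sqrt(sum(apply(pts, 2, var)))

  # instantaneous stride time per step (sum of the step and its successor;
  # the last step reuses its predecessor)
  st <- steps$step_times
  stride_at <- c(st[-length(st)] + st[-1], st[length(st) - 1] + st[length(st)])
  qb <- quantile(stride_at, stride_pct, names = FALSE)

  # candidate pool per phase: points on annotated steps within the phase
  # tolerance (clipped at the step boundaries, so identical strides give
  # exactly zero candidate distances)
  dphi <- abs(phi - phase)
  cand_all <- which(!is.na(dphi) & dphi <= phase_tol)
  cand_step <- stp[cand_all]

  grid_j0 <- as.integer(round(100 * phase))
  grid <- grid_j0:100 / 100
  tpts <- t(pts)                       # points in columns for the C++ kernels
  acc_curve <- numeric(length(grid))
  n_used <- 0L
  n_excluded <- 0L
  total_refs <- 0L

  for (k in seq_len(n_steps - 1L)) {
    ref <- on[k] + as.integer(round(phase * (on[k + 1] - on[k])))
    horizon <- on[k + 1] - ref
    if (horizon < 2L || ref + horizon > npts) next
    total_refs <- total_refs + 1L
    if (stride_at[k] < qb[1] || stride_at[k] > qb[2]) {
      n_excluded <- n_excluded + 1L
      next
    }
    sel <- abs(cand_step - k) > theiler
    cand <- cand_all[sel]
    cs <- cand_step[sel]
    keep <- cand + horizon <= npts
    cand <- cand[keep]; cs <- cs[keep]
    if (length(cand) < min_neighbors) { n_excluded <- n_excluded + 1L; next }
    d0 <- cpp_point_distances(tpts, ref - 1L, cand - 1L)
    ok <- d0 <= radius
    cand <- cand[ok]; d0 <- d0[ok]; cs <- cs[ok]
    # one neighbour trajectory per stride: the closest eligible point
    o <- order(cs, d0)
    nb <- cand[o][!duplicated(cs[o])]
    if (length(nb) < min_neighbors) { n_excluded <- n_excluded + 1L; next }

    D <- cpp_trace_distances(tpts, ref - 1L, nb - 1L, horizon)
    curve <- rowMeans(D)
    tk <- phase + (0:horizon) / horizon * (1 - phase)
    acc_curve <- acc_curve + approx(tk, curve, xout = grid, rule = 2)$y
    n_used <- n_used + 1L
  }

  if (n_used == 0L) {
    return(structure(list(phase = phase, t = grid, log_d = rep(NA_real_, length(grid)),
                          n_refs = 0L, excluded_fraction = 1,
                          degenerate = TRUE), class = "reaction_curve"))
  }
  mean_curve <- acc_curve / n_used
  degenerate <- mean_curve[1] <= 1e-12
  log_d <- suppressWarnings(log(mean_curve))
  log_d[!is.finite(log_d)] <- NA_real_
  structure(list(phase = phase, t = grid, log_d = log_d,
                 n_refs = n_used,
                 excluded_fraction = n_excluded / max(total_refs, 1L),
                 degenerate = degenerate),
            class = "reaction_curve")
}

#' Local dynamic stability by regression slope
#'
#' Ordinary least-squares slope of the log mean reaction distance over the
#' first 10% of the step cycle after the initial phase, in units of
#' log-distance per step-normalised time.
#'
#' @param curve a [reaction_curve()].
#' @return Numeric lambda (NA if the curve is degenerate or has fewer than 3
#'   usable grid points).
#' @export
lambda_eq1 <- function(curve) {
  if (isTRUE(curve$degenerate)) return(NA_real_)
  sel <- curve$t <= curve$phase + 0.1 + 1e-9
  t <- curve$t[sel]; y <- curve$log_d[sel]
  ok <- is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Local dynamic stability by log distance ratio
#'
#' `lambda = (1/t_n) * log(d(t_n)/d(0))` with `t_n = 0.1` of the step cycle
#' (step-normalised time), evaluated on the mean reaction curve.
#'
#' @param curve a [reaction_curve()].
#' @return Numeric lambda (NA when the initial distance is zero/undefined).
#' @export
lambda_eq2 <- function(curve) {
  if (isTRUE(curve$degenerate)) return(NA_real_)
  i0 <- 1L
  i1 <- which(abs(curve$t - (curve$phase + 0.1)) < 1e-9)
  if (length(i1) != 1) return(NA_real_)
  y0 <- curve$log_d[i0]; y1 <- curve$log_d[i1]
  if (!is.finite(y0) || !is.finite(y1)) return(NA_real_)
  (y1 - y0) / 0.1
}

#' Phase-dependent lambda for one bout and one embedding
#'
#' @param traj a `state_trajectory`.
#' @param steps the bout `step_series`.
#' @param phases phases to evaluate (fractions of the step cycle).
#' @param ... passed to [reaction_curve()].
#' @return data.frame: phase, eq (1 or 2), lambda, excluded_fraction.
#' @export
bout_phase_lambda <- function(traj, steps, phases = LDS_PHASES, ...) {
  rows <- lapply(phases, function(p) {
    rc <- reaction_curve(traj, steps, p, ...)
    data.frame(phase = p, eq = c(1L, 2L),
               lambda = c(lambda_eq1(rc), lambda_eq2(rc)),
               excluded_fraction = rc$excluded_fraction)
  })
  do.call(rbind, rows)
}

#' Subject-level lambda: median across bouts
#'
#' @param bout_lambdas numeric vector of per-bout lambda values (NAs allowed).
#' @return Median of the finite values; NA (with all bouts missing) otherwise.
#' @export
subject_lambda <- function(bout_lambdas) {
  v <- bout_lambdas[is.finite(bout_lambdas)]
  if (length(v) == 0) return(NA_real_)
  median(v)
}

#' Wolf's largest Lyapunov exponent
#'
#' Wolf's trajectory-tracking algorithm on a univariate signal embedded in a
#' delayed coordinate space: the nearest neighbour of the fiducial trajectory
#' is followed, `log(L'/L)` is accumulated at each evolution step, neighbours
#' are replaced through an orientation-preserving search (angle below
#' `max_angle`, distance inside an annulus), and the sum is divided by the
#' elapsed time.
#'
#' @param x numeric signal (one acceleration axis of a bout).
#' @param sample_rate sampling rate (Hz).
#' @param dim embedding dimension.
#' @param lag delay in samples.
#' @param evolve_time evolution time between replacement attempts (s).
#' @param theiler temporal neighbour exclusion (samples).
#' @param min_dist_frac,max_dist_frac replacement annulus as fractions of the
#'   attractor extent.
#' @param max_angle maximum replacement angle (degrees).
#' @param min_length minimum signal length (samples).
#' @return lambda in 1/s (NA for too-short input).
#' @export
wolf_lambda <- function(x, sample_rate, dim = 6, lag = 8,
                        evolve_time = 0.1, theiler = round(sample_rate),
                        min_dist_frac = 1e-4, max_dist_frac = 0.1,
                        max_angle = 30, min_length = 3000) {
  n <- length(x)
  if (n < max(min_length, (dim - 1) * lag + 10)) return(NA_real_)
  m <- n - (dim - 1) * lag
  pts <- vapply(0:(dim - 1), function(j) x[(1 + j * lag):(m + j * lag)],
                numeric(m))
  ext <- sqrt(sum(apply(pts, 2, var)))
  if (ext == 0) return(NA_real_)
  res <- cpp_wolf(t(pts), dt = 1 / sample_rate,
                  evolve = max(1L, as.integer(round(evolve_time * sample_rate))),
                  theiler = as.integer(theiler),
                  dmin = min_dist_frac * ext, dmax = max_dist_frac * ext,
                  max_angle = max_angle * pi / 180)
  res$lambda
}
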