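# Daubechies extremal-phase scaling filter with 4 vanishing moments (8 taps).
# Orthonormal: sum(h^2) = 1, sum(h) = sqrt(2).
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)

# One periodised synthesis step for the approximation branch: maps level-(j)
# approximation coefficients (length m) to level-(j-1) coefficients (2m),
# with zero detail coefficients.
dwt_synth_approx <- function(a) {
  m <- length(a)
  n <- 2L * m
  x <- numeric(n)
  L <- length(DB4_H)
  for (i in seq_len(L)) {
    idx <- ((2L * (seq_len(m) - 1L) + (i - 1L)) %% n) + 1L
    x[idx] <- x[idx] + DB4_H[i] * a
  }
  x
}

# Level-J scaling function sampled on a circle of length M (unit coefficient
# at slot 1).
scaling_function <- function(M, J) {
  a <- numeric(M / 2^J)
  a[1] <- 1
  for (j in seq_len(J)) a <- dwt_synth_approx(a)
  a
}

# Basis of coarse-scale (level-J) scaling-function translates restricted to a
# window of length n. The circle is made wide enough that no translate wraps
# across both window ends, so the restricted basis reproduces polynomials up
# to degree 3 exactly on the window. Returns the QR factorisation of the
# basis, cached per (n, J).
.detrend_cache <- new.env(parent = emptyenv())

detrend_basis_qr <- function(n, J) {
  key <- paste0(n, "_", J)
  hit <- .detrend_cache[[key]]
  if (!is.null(hit)) return(hit)
  sc <- 2^J
  support <- (length(DB4_H) - 1L) * sc
  M <- ceiling((n + support) / sc) * sc
  phi <- scaling_function(M, J)
  K <- M / sc
  cols <- vector("list", K)
  for (k in seq_len(K)) {
    shifted <- phi[((seq_len(M) - 1L - (k - 1L) * sc) %% M) + 1L]
    w <- shifted[seq_len(n)]
    if (any(w != 0)) cols[[k]] <- w
  }
  B <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  qrB <- qr(B)
  .detrend_cache[[key]] <- qrB
  qrB
}

# Dyadic level whose scale first exceeds factor * stride period. The factor
# trades trend removal against stop-band leakage: at 2.5 the approximation
# space absorbs < 0.5% of a 2 Hz step-frequency component while still
# removing fluctuations slower than ~5 s.
detrend_level <- function(sample_rate, stride_period, factor = 2.5) {
  floor(log2(factor * stride_period * sample_rate)) + 1L
}

#' Orthogonal wavelet detrending
#'
#' Removes the component of a signal living in the coarse-scale wavelet
#' approximation space (Daubechies-4, dyadic scales slower than
#' `2.5 * stride_period`) by orthogonal projection. Intrastep variation is
#' preserved while interstride (including nonlinear) trends are removed. The
#' operation is an exact orthogonal projection: detrended + trend reconstructs
#' the input, the two parts are orthogonal, and detrending is idempotent.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param sample_rate sampling rate (Hz).
#' @param stride_period estimated stride period (s); selects the dyadic
#'   cut-off scale.
#' @return Detrended signal, same shape as `x`, with the removed trend in
#'   attribute `"trend"`.
#' @export
wavelet_detrend <- function(x, sample_rate, stride_period = 1) {
  if (is.matrix(x)) {
    out <- x
    trend <- x
    for (j in seq_len(ncol(x))) {
      dj <- wavelet_detrend(x[, j], sample_rate, stride_period)
      out[, j] <- dj
      trend[, j] <- attr(dj, "trend")
    }
    attr(out, "trend") <- trend
    return(out)
  }
  if (!all(is.finite(x))) stop_data("non-finite input to wavelet_detrend")
  n <- length(x)
  if (n < 4 * stride_period * sample_rate)
    stop_data("signal shorter than 4 stride periods")
  J <- detrend_level(sample_rate, stride_period)
  qrB <- detrend_basis_qr(n, J)
  trend <- qr.fitted(qrB, x)
  out <- x - trend
  attr(out, "trend") <- trend
  out
}

#' Integrate acceleration to intrastep velocity
#'
#' Cumulative trapezoidal integration per axis followed by the same orthogonal
#' wavelet detrend, which removes integration drift while preserving
#' intrastep velocity variation.
#'
#' @param acc detrended acceleration, vector or matrix (m/s^2).
#' @param sample_rate sampling rate (Hz).
#' @param stride_period stride-period estimate (s) for the detrend scale.
#' @return Velocity (m/s), same shape as `acc`.
#' @export
integrate_to_velocity <- function(acc, sample_rate, stride_period = 1) {
  if (!all(is.finite(acc))) stop_data("non-finite input to integrate_to_velocity")
  cumtrapz <- function(a) {
    n <- length(a)
    c(0, cumsum((a[-1] + a[-n]) / 2)) / sample_rate
  }
  if (is.matrix(acc)) v <- apply(acc, 2, cumtrapz) else v <- cumtrapz(acc)
  v <- wavelet_detrend(v, sample_rate, stride_period)
  attr(v, "trend") <- NULL
  v
}

# peak finding with prominence: returns indices of local maxima with
# prominence >= min_prom, thinned to a minimum separation (keeping higher
# peaks). Plateau ties break to the earliest sample.
find_peaks <- function(x, min_sep, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]; h <- x[p]
    lmin <- h; j <- p - 1L
    while (j >= 1 && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    left_base <- lmin
    rmin <- h; j <- p + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    right_base <- rmin
    keep[i] <- (h - max(left_base, right_base)) >= min_prom
  }
  cand <- cand[keep]
  if (length(cand) == 0) return(integer(0))
  ord <- order(x[cand], decreasing = TRUE)
  chosen <- integer(0)
  for (p in cand[ord]) {
    if (all(abs(chosen - p) >= min_sep)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Detect step onsets from vertical velocity
#'
#' Step onsets are the local maxima of the vertical velocity, with a minimum
#' peak separation of `min_separation` seconds and a prominence floor of
#' `prominence_frac` times the signal SD.
#'
#' @param v velocity matrix (columns AP/ML/V) or the vertical velocity vector.
#' @param sample_rate sampling rate (Hz).
#' @param min_separation minimum distance between step onsets (s).
#' @param prominence_frac prominence floor as a fraction of `sd(v_V)`.
#' @param min_steps bouts with fewer detected steps are rejected with a
#'   classed error (`gaitlds_bout_rejected`).
#' @return A `step_series`: list with `onsets` (1-based sample indices),
#'   `times` (s), `step_times`, `stride_times` (sums of consecutive step
#'   pairs) and `mean_step_time`.
#' @export
detect_steps <- function(v, sample_rate, min_separation = 0.25,
                         prominence_frac = 0.1, min_steps = 10) {
  vv <- if (is.matrix(v)) v[, ncol(v)] else v
  s <- sd(vv)
  if (!is.finite(s) || s == 0) reject_bout("flat vertical velocity; no steps")
  peaks <- find_peaks(vv, min_sep = min_separation * sample_rate,
                      min_prom = prominence_frac * s)
  if (length(peaks) < min_steps)
    reject_bout("fewer than ", min_steps, " steps detected")
  step_times <- diff(peaks) / sample_rate
  stride_times <- if (length(step_times) >= 2)
    step_times[-length(step_times)] + step_times[-1] else numeric(0)
  structure(
    list(onsets = peaks, times = (peaks - 1) / sample_rate,
         step_times = step_times, stride_times = stride_times,
         mean_step_time = mean(step_times), sample_rate = sample_rate),
    class = "step_series")
}

#' Estimate the stride period from an acceleration signal
#'
#' Dominant peak of the power spectrum in the locomotor band; if the peak
#' falls in the step band (>= `step_band_min` Hz) it is interpreted as the
#' step frequency and the stride period is twice its inverse.
#'
#' @param x acceleration vector (typically the V axis).
#' @param sample_rate sampling rate (Hz).
#' @param band search band (Hz).
#' @param step_band_min frequencies above this are treated as step frequency.
#' @return Stride period in seconds.
#' @export
estimate_stride_period <- function(x, sample_rate, band = c(0.3, 3.5),
                                   step_band_min = 1.4) {
  ps <- welch_psd(x, sample_rate)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) stop_data("no spectral support in locomotor band")
  f <- ps$freq[sel][which.max(ps$power[sel])]
  if (f >= step_band_min) 2 / f else 1 / f
}

#' Preprocess one walking bout
#'
#' Wavelet-detrends the bout acceleration, integrates to intrastep 3D
#' velocity, and detects step onsets.
#'
#' @param acc bout acceleration matrix (AP/ML/V).
#' @param sample_rate sampling rate (Hz).
#' @return list: `acc` (detrended), `vel`, `steps` ([detect_steps()] result),
#'   `stride_period`.
#' @export
preprocess_bout <- function(acc, sample_rate) {
  sp <- estimate_stride_period(acc[, 3], sample_rate)
  acc_d <- wavelet_detrend(acc, sample_rate, sp)
  attr(acc_d, "trend") <- NULL
  vel <- integrate_to_velocity(acc_d, sample_rate, sp)
  steps <- detect_steps(vel, sample_rate)
  list(acc = acc_d, vel = vel, steps = steps, stride_period = sp)
}
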