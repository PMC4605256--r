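#' Walking-bout detection parameters
#'
#' Two-filter architecture: a window passes if (i) the standard deviation of
#' the acceleration vector magnitude exceeds `amplitude_threshold` and (ii)
#' the fraction of spectral power inside the locomotor band exceeds
#' `energy_fraction`. Passing windows are merged, gaps up to `bridge_gap` are
#' bridged, and only merged segments of at least `min_duration` are kept.
#'
#' @param window window length (s).
#' @param overlap fractional window overlap.
#' @param amplitude_threshold SD of the vector magnitude, in g.
#' @param band locomotor frequency band (Hz).
#' @param total_band reference band for the energy fraction (Hz).
#' @param energy_fraction minimum fraction of `total_band` power in `band`.
#' @param bridge_gap maximum non-walking gap bridged (s).
#' @param min_duration minimum bout duration (s).
#' @return list of class `bout_params`.
#' @export
bout_params <- function(window = 5, overlap = 0.5,
                        amplitude_threshold = 0.03,
                        band = c(0.5, 3.0), total_band = c(0, 10),
                        energy_fraction = 0.5,
                        bridge_gap = 2.5, min_duration = 60) {
  structure(as.list(environment()), class = "bout_params")
}

#' Detect walking bouts in a triaxial recording
#'
#' @param rec a [triaxial_recording] of dynamic (gravity-free) acceleration.
#' @param params a [bout_params()].
#' @return data.frame with one row per bout: `start`, `end` (0-based,
#'   half-open sample indices), `start_s`, `end_s`, `duration`. Zero rows if
#'   nothing qualifies.
#' @export
detect_walking_bouts <- function(rec, params = bout_params()) {
  if (!inherits(rec, "triaxial_recording")) stop_data("rec must be a triaxial_recording")
  acc <- rec$acc
  if (!all(is.finite(acc))) stop_data("non-finite samples in recording")
  fs <- rec$sample_rate
  n <- nrow(acc)
  win <- round(params$window * fs)
  empty <- data.frame(start = integer(0), end = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      duration = numeric(0))
  if (n < win) return(empty)

  step <- max(1L, round(win * (1 - params$overlap)))
  starts <- seq(1L, n - win + 1L, by = step)
  mag <- sqrt(rowSums(acc^2))
  g <- 9.80665

  freq <- seq(0, fs / 2, length.out = win %/% 2 + 1)
  in_band <- freq >= params$band[1] & freq <= params$band[2]
  in_total <- freq >= params$total_band[1] & freq <= params$total_band[2]

  pass <- logical(length(starts))
  for (i in seq_along(starts)) {
    rows <- starts[i]:(starts[i] + win - 1L)
    if (sd(mag[rows]) / g <= params$amplitude_threshold) next
    # spectral energy summed over the three axes (the magnitude itself
    # oscillates at twice the locomotor frequencies)
    pw <- 0
    for (j in 1:3) {
      seg <- acc[rows, j]
      p <- Mod(fft(seg - mean(seg)))^2
      pw <- pw + p[seq_len(win %/% 2 + 1)]
    }
    tot <- sum(pw[in_total])
    if (tot > 0 && sum(pw[in_band]) / tot > params$energy_fraction) pass[i] <- TRUE
  }

  walking <- logical(n)
  for (i in which(pass)) walking[starts[i]:(starts[i] + win - 1L)] <- TRUE

  # bridge short gaps
  r <- rle(walking)
  gap <- round(params$bridge_gap * fs)
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    fix <- interior[!r$values[interior] & r$lengths[interior] <= gap]
    r$values[fix] <- TRUE
  }
  walking <- inverse.rle(r)

  r <- rle(walking)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_duration * fs
  if (!any(keep)) return(empty)
  begins <- begins[keep]; ends <- ends[keep]

  # refine boundaries (window granularity smears them by up to half a
  # window): walk each edge to where a 1-s rolling SD of the magnitude
  # crosses the amplitude threshold
  h <- max(2L, round(fs / 2))
  cs <- cumsum(c(0, mag)); cs2 <- cumsum(c(0, mag^2))
  roll_pass <- function(i) {
    a <- max(1L, i - h); b <- min(n, i + h)
    m <- (cs[b + 1] - cs[a]) / (b - a + 1)
    v <- (cs2[b + 1] - cs2[a]) / (b - a + 1) - m^2
    sqrt(max(v, 0)) / g > params$amplitude_threshold
  }
  for (i in seq_along(begins)) {
    s <- begins[i]
    while (s > 1L && roll_pass(s - 1L)) s <- s - 1L
    while (s < ends[i] && !roll_pass(s)) s <- s + 1L
    e <- ends[i]
    while (e < n && roll_pass(e + 1L)) e <- e + 1L
    while (e > s && !roll_pass(e)) e <- e - 1L
    begins[i] <- s; ends[i] <- e
  }
  ok <- (ends - begins + 1L) >= params$min_duration * fs
  begins <- begins[ok]; ends <- ends[ok]
  if (length(begins) == 0) return(empty)
  data.frame(start = begins - 1L,              # 0-based half-open
             end = ends,
             start_s = (begins - 1L) / fs,
             end_s = ends / fs,
             duration = (ends - begins + 1L) / fs)
}

#' Extract one bout's acceleration from a recording
#'
#' @param rec a [triaxial_recording].
#' @param bout one row of the table returned by [detect_walking_bouts()].
#' @return acceleration matrix (samples x AP/ML/V).
#' @export
bout_acc <- function(rec, bout) {
  rec$acc[(bout$start + 1L):bout$end, , drop = FALSE]
}

#' Bout table across a cohort
#'
#' @param recordings named list of [triaxial_recording] objects.
#' @param params a [bout_params()].
#' @return data.frame: subject_id, bout_idx, start_s, end_s.
#' @export
cohort_bout_table <- function(recordings, params = bout_params()) {
  out <- lapply(names(recordings), function(id) {
    b <- detect_walking_bouts(recordings[[id]], params)
    if (nrow(b) == 0) return(NULL)
    data.frame(subject_id = id, bout_idx = seq_len(nrow(b)) - 1L,
               start_s = b$start_s, end_s = b$end_s)
  })
  do.call(rbind, out)
}
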