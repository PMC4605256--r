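# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: plain loops, closed forms, and base-R model
# fits.

# ---- Lorenz system: trajectory and Benettin variational oracle -------------

lorenz_deriv <- function(s, sigma = 10, rho = 28, beta = 8 / 3) {
  c(sigma * (s[2] - s[1]), s[1] * (rho - s[3]) - s[2], s[1] * s[2] - beta * s[3])
}

rk4_step <- function(s, h, f) {
  k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
  s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

gen_lorenz <- function(n, h = 0.01, transient = 500) {
  s <- c(1, 1, 20)
  for (i in seq_len(transient)) s <- rk4_step(s, h, lorenz_deriv)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- rk4_step(s, h, lorenz_deriv)
    out[i, ] <- s
  }
  out
}

# largest Lyapunov exponent by integrating the variational equation along the
# same trajectory, renormalising the tangent vector each step
benettin_lorenz <- function(n, h = 0.01, transient = 500,
                            sigma = 10, rho = 28, beta = 8 / 3) {
  jac <- function(s) matrix(c(-sigma, sigma, 0,
                              rho - s[3], -1, -s[1],
                              s[2], s[1], -beta), 3, 3, byrow = TRUE)
  f2 <- function(sv) {
    st <- sv[1:3]
    c(lorenz_deriv(st), jac(st) %*% sv[4:6])
  }
  s <- c(1, 1, 20)
  for (i in seq_len(transient)) s <- rk4_step(s, h, lorenz_deriv)
  sv <- c(s, 1, 0, 0)
  acc <- 0
  for (i in seq_len(n)) {
    sv <- rk4_step(sv, h, f2)
    nv <- sqrt(sum(sv[4:6]^2))
    acc <- acc + log(nv)
    sv[4:6] <- sv[4:6] / nv
  }
  acc / (n * h)
}

# ---- small helpers ---------------------------------------------------------

# fabricate a step_series without running detection
make_steps <- function(onsets, fs) {
  step_times <- diff(onsets) / fs
  structure(list(
    onsets = onsets, times = (onsets - 1) / fs, step_times = step_times,
    stride_times = step_times[-length(step_times)] + step_times[-1],
    mean_step_time = mean(step_times), sample_rate = fs),
    class = "step_series")
}

# closed-form OLS slope
ols_slope <- function(t, y) sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)

# a reaction_curve object with prescribed log-distances
make_curve <- function(t, log_d, phase = 0) {
  structure(list(phase = phase, t = t, log_d = log_d, n_refs = 10L,
                 excluded_fraction = 0, degenerate = FALSE),
            class = "reaction_curve")
}

# dominant period by autocorrelation (oracle for the mean step time)
acf_period <- function(x, fs, min_s = 0.3, max_s = 1.0) {
  lags <- seq(round(min_s * fs), round(max_s * fs))
  a <- stats::acf(x, lag.max = max(lags), plot = FALSE)$acf[-1]
  lags[which.max(a[lags])] / fs
}

# brute-force average mutual information with equiprobable bins (independent
# implementation: explicit cell counting)
ami_oracle <- function(x, max_lag, bins = 16) {
  n <- length(x)
  qs <- quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
  qs[1] <- -Inf; qs[bins + 1] <- Inf
  bx <- cut(x, qs, labels = FALSE)
  vapply(seq_len(max_lag), function(tau) {
    a <- bx[1:(n - tau)]; b <- bx[(1 + tau):n]
    m <- n - tau
    mi <- 0
    for (i in unique(a)) for (j in unique(b)) {
      pij <- sum(a == i & b == j) / m
      if (pij > 0) mi <- mi + pij * log(pij / (sum(a == i) / m * sum(b == j) / m))
    }
    mi
  }, numeric(1))
}

# eigen-decomposition based PLS1 (oracle for NIPALS): the weight of each
# component is the dominant eigenvector of X'yy'X
pls1_eigen_oracle <- function(X, y, ncomp) {
  Xd <- scale(X)
  yd <- y - mean(y)
  W <- NULL; Tm <- NULL; P <- NULL; C <- numeric(0)
  for (a in seq_len(ncomp)) {
    M <- crossprod(Xd, yd) %*% crossprod(yd, Xd)   # p x p, rank 1
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t_a <- Xd %*% w
    c_a <- sum(t_a * yd) / sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / sum(t_a^2)
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - c_a * t_a
    W <- cbind(W, w); Tm <- cbind(Tm, t_a); P <- cbind(P, p_a); C <- c(C, c_a)
  }
  list(W = W, T = Tm, P = P, C = C)
}

# all-pairs AUC oracle (concordant pairs + half ties)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# ICC(A,1) oracle through an explicit two-way ANOVA fit
icc_aov_oracle <- function(test, retest) {
  n <- length(test); k <- 2
  d <- data.frame(y = c(test, retest),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  av <- summary(aov(y ~ subj + rater, data = d))[[1]]
  msr <- av["subj", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# O(n^2) oracle for the mean initial reaction distance: exhaustive
# re-implementation of the neighbour rules with plain loops
d0_oracle <- function(pts, phase_v, step_v, steps, phase, radius, phase_tol,
                      theiler, min_neighbors, stride_pct = c(0.05, 0.95)) {
  on <- steps$onsets
  n_steps <- length(on) - 1
  st <- steps$step_times
  stride_at <- c(st[-length(st)] + st[-1], st[length(st) - 1] + st[length(st)])
  qb <- quantile(stride_at, stride_pct, names = FALSE)
  vals <- c()
  for (k in seq_len(n_steps - 1)) {
    ref <- on[k] + as.integer(round(phase * (on[k + 1] - on[k])))
    horizon <- on[k + 1] - ref
    if (horizon < 2 || ref + horizon > nrow(pts)) next
    if (stride_at[k] < qb[1] || stride_at[k] > qb[2]) next
    best <- list()
    for (i in seq_len(nrow(pts))) {
      if (is.na(phase_v[i])) next
      if (abs(phase_v[i] - phase) > phase_tol) next
      sv <- step_v[i]
      if (abs(sv - k) <= theiler) next
      if (i + horizon > nrow(pts)) next
      d <- sqrt(sum((pts[ref, ] - pts[i, ])^2))
      if (d > radius) next
      key <- as.character(sv)
      if (is.null(best[[key]]) || d < best[[key]]) best[[key]] <- d
    }
    if (length(best) < min_neighbors) next
    vals <- c(vals, mean(unlist(best)))
  }
  mean(vals)
}

# small synthetic cohort config used by several tests
test_cohort_config <- function(...) {
  gait_sim_config(n_subjects_per_group = c(faller = 2, nonfaller = 2),
                  bouts_per_subject = 2, bout_duration = 60, seed = 11, ...)
}
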