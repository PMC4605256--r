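#' Fit a PLS1 discriminant model by NIPALS
#'
#' Classical NIPALS partial least squares with a single response: per
#' component the X-weight is `w = X'y / |X'y|`, scores `t = Xw`, y-loading
#' `c = t'y / t't`, X-loading `p = X't / t't`, followed by deflation of `X`
#' and `y`. The regression vector `B = W (P'W)^{-1} c` maps z-scored
#' predictors to the class code.
#'
#' @param X predictor matrix (subjects x features).
#' @param y numeric class code (0 = nonfaller, 1 = faller).
#' @param ncomp number of latent variables.
#' @param center,scale standardise columns of `X` (z-scores) before fitting.
#' @param on_constant what to do with zero-variance predictor columns:
#'   `"error"` (default; z-scoring upstream should prevent them) or
#'   `"zero"` (column enters as all-zero z-scores, hence weight 0).
#' @return An object of class `pls_model`: weights `W`, scores `T`, loadings
#'   `P`, y-loadings `C`, regression vector `B`, the transform (`means`,
#'   `sds`, `y_mean`) and fitted scores.
#' @export
fit_pls_nipals <- function(X, y, ncomp = 4, center = TRUE, scale = TRUE,
                           on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop_data("missing values in X or y")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_data("length(y) != nrow(X)")
  means <- if (center) colMeans(X) else rep(0, p)
  sds <- if (scale) apply(X, 2, sd) else rep(1, p)
  if (any(sds == 0)) {
    if (on_constant == "error") stop_data("zero-variance predictor column")
    sds[sds == 0] <- 1
  }
  Xz <- sweep(sweep(X, 2, means), 2, sds, "/")
  y_mean <- mean(y)

  Xd <- Xz
  yd <- y - y_mean
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Tm <- matrix(0, n, 0)
  C <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("rank exhausted after ", a - 1, " components")
      break
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    c_a <- sum(t_a * yd) / tt
    p_a <- crossprod(Xd, t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - c_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, t_a)
    C <- c(C, c_a)
  }
  B <- W %*% solve(crossprod(P, W), C)
  structure(
    list(W = W, P = P, T = Tm, C = C, B = B,
         ncomp = ncol(W), means = means, sds = sds, y_mean = y_mean,
         Xz = Xz, fitted = as.numeric(y_mean + Xz %*% B)),
    class = "pls_model")
}

#' Predict class scores from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix on the original scale.
#' @param ... unused.
#' @return numeric vector of continuous class scores.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xz <- sweep(sweep(as.matrix(newdata), 2, object$means), 2, object$sds, "/")
  as.numeric(object$y_mean + Xz %*% object$B)
}

#' Target projection of a PLS model
#'
#' Projects the model onto its single predictive direction: the target
#' projection score `V = Xz B / |B|` gives one discriminant score per
#' subject (positive direction = faller class), and the TP loading of each
#' feature is its correlation with `V`, hence lies in `[-1, 1]` and ranks
#' the feature's contribution to the discrimination.
#'
#' @param model a fitted `pls_model`.
#' @return list with `V` (scores) and `loadings` (named, in `[-1, 1]`).
#' @export
target_projection <- function(model) {
  bn <- sqrt(sum(model$B^2))
  if (bn < 1e-12) stop_data("degenerate model: B ~ 0")
  V <- as.numeric(model$Xz %*% model$B) / bn
  loadings <- suppressWarnings(as.numeric(cor(model$Xz, V)))
  loadings[!is.finite(loadings)] <- 0   # constant columns carry no signal
  names(loadings) <- colnames(model$Xz)
  list(V = V, loadings = loadings)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; AUC by the rank (Mann-Whitney)
#' identity, so ties contribute 1/2.
#'
#' @param scores continuous classifier scores (larger = more positive).
#' @param labels 0/1 class labels.
#' @return list with `roc` (data.frame fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_data("both classes required for ROC")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(th, function(s) sum(scores >= s & labels == 0) / n0, numeric(1)),
    tpr = vapply(th, function(s) sum(scores >= s & labels == 1) / n1, numeric(1)))
  list(roc = roc, auc = auc)
}

#' Leave-one-out cross-validated PLS-DA metrics
#'
#' For every held-out subject the z-scoring and the PLS fit are recomputed on
#' the training fold only (no leakage); the held-out continuous score feeds
#' the ROC, and classes are assigned at the midpoint of the 0/1 class codes.
#'
#' @param X predictor matrix on the original scale.
#' @param y 0/1 class code (1 = faller).
#' @param ncomp number of latent variables.
#' @param threshold decision threshold on the predicted code.
#' @return list of class `cv_metrics`: sensitivity, specificity, auc, error,
#'   per-subject `scores`, `roc`.
#' @export
cross_validate <- function(X, y, ncomp = 4, threshold = 0.5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) stop_data(">= 2 subjects per class required")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls_nipals(X[-i, , drop = FALSE], y[-i], ncomp = ncomp,
                          on_constant = "zero")
    scores[i] <- predict(fit, X[i, , drop = FALSE])
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  ra <- roc_auc(scores, y)
  structure(
    list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         auc = ra$auc, error = (fp + fn) / n,
         scores = scores, roc = ra$roc, confusion = c(tp = tp, fp = fp,
                                                      tn = tn, fn = fn)),
    class = "cv_metrics")
}

#' Intraclass correlation, absolute agreement, single measures
#'
#' Two-way mixed-effects ICC(A,1) for a test/retest pair (k = 2 raters),
#' with the 95% confidence interval from the F-distribution bounds
#' (McGraw & Wong parameterisation).
#'
#' @param test,retest paired measurement vectors.
#' @param conf confidence level.
#' @return list of class `icc_result`: `icc`, `lower`, `upper`, `n`.
#' @export
icc_absolute <- function(test, retest, conf = 0.95) {
  ok <- is.finite(test) & is.finite(retest)
  x <- cbind(test[ok], retest[ok])
  n <- nrow(x); k <- 2
  if (n < 5) stop_data("ICC requires >= 5 paired subjects")
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  if (var(row_m) == 0) stop_data("zero between-subject variance: ICC undefined")
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- sum(sweep(sweep(x, 1, row_m), 2, col_m - g)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, lower = lower, upper = upper, n = n),
            class = "icc_result")
}

#' Per-feature two-group comparison
#'
#' Two-sided Mann-Whitney U test per feature (no multiple-testing
#' adjustment; raw p-values are reported).
#'
#' @param values data.frame or matrix of per-subject feature values.
#' @param labels group factor/character vector (two levels).
#' @return data.frame: feature, p, and group means and SDs.
#' @export
group_compare <- function(values, labels) {
  values <- as.data.frame(values)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_data("exactly two groups required")
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  rows <- lapply(names(values), function(f) {
    v <- values[[f]]
    a <- v[labels == g1 & is.finite(v)]
    b <- v[labels == g2 & is.finite(v)]
    p <- if (length(a) >= 2 && length(b) >= 2)
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value) else NA_real_
    data.frame(feature = f, p = p,
               mean_1 = mean(a), sd_1 = sd(a),
               mean_2 = mean(b), sd_2 = sd(b))
  })
  out <- do.call(rbind, rows)
  names(out)[3:6] <- c(paste0("mean_", g1), paste0("sd_", g1),
                       paste0("mean_", g2), paste0("sd_", g2))
  out
}
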