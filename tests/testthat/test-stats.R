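test_that("NIPALS PLS1 matches the eigen-based oracle up to sign", {
  set.seed(51)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  fit <- fit_pls_nipals(X, y, ncomp = 3)
  or <- pls1_eigen_oracle(X, y, ncomp = 3)
  for (a in 1:3) {
    s <- sign(sum(fit$W[, a] * or$W[, a]))
    expect_equal(fit$W[, a], s * or$W[, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$T[, a], s * or$T[, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # score orthogonality
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # accumulated regression vector reproduces the component-wise fit
  yhat_comp <- fit$y_mean + as.numeric(fit$T %*% fit$C)
  expect_equal(fit$fitted, yhat_comp, tolerance = 1e-8)
})

test_that("PLS handles perfect predictors and irrelevant columns", {
  y <- c(rep(0, 5), rep(1, 5))
  X <- cbind(v = y * 2 + 3)
  fit <- fit_pls_nipals(X, y, ncomp = 1)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_equal(predict(fit, X), y, tolerance = 1e-10)

  set.seed(52)
  # a column orthogonal to y and to the other columns gets ~zero weight
  z <- c(1, -1, 1, -1, 0, 1, -1, 1, -1, 0)  # orthogonal to centred y
  X2 <- cbind(y + rnorm(10, sd = 0.01), z)
  fit2 <- fit_pls_nipals(X2, y, ncomp = 1)
  expect_lt(abs(fit2$W[2, 1]), 1e-10)

  expect_error(fit_pls_nipals(cbind(rep(1, 10)), y),
               class = "gaitlds_data_error")
  expect_warning(fit_pls_nipals(cbind(y, y), y, ncomp = 4), "rank")
})

test_that("target projection ranks features by discriminant value", {
  set.seed(53)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 1e-8),
             matrix(rnorm(n * 4), n, 4))
  fit <- fit_pls_nipals(X, y, ncomp = 2)
  tp <- target_projection(fit)
  expect_equal(abs(unname(tp$loadings["sig"])), 1, tolerance = 1e-3)
  # positive direction = faller (class 1)
  expect_gt(mean(tp$V[y == 1]), mean(tp$V[y == 0]))

  # one-component model: TP loadings proportional to the X-loadings p1
  fit1 <- fit_pls_nipals(X, y, ncomp = 1)
  tp1 <- target_projection(fit1)
  p1 <- as.numeric(fit1$P[, 1])
  cors <- abs(cor(tp1$loadings, p1))
  expect_gt(cors, 1 - 1e-10)

  # pure-noise feature: small loading at large n
  set.seed(54)
  n2 <- 400
  y2 <- rep(c(0, 1), each = n2 / 2)
  X3 <- cbind(y2 + rnorm(n2, sd = 0.3), noise = rnorm(n2))
  tp3 <- target_projection(fit_pls_nipals(X3, y2, ncomp = 1))
  expect_lt(abs(unname(tp3$loadings["noise"])), 0.2)
})

test_that("ROC/AUC match the all-pairs oracle and tie conventions", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(55)
  s <- round(rnorm(20), 1)  # some ties
  l <- rbinom(20, 1, 0.5); l[1:2] <- c(0, 1)
  ra <- roc_auc(s, l)
  expect_equal(ra$auc, auc_oracle(s, l), tolerance = 1e-12)
  expect_equal(roc_auc(-s, l)$auc, 1 - ra$auc, tolerance = 1e-12)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  expect_error(roc_auc(s, rep(1, 20)), class = "gaitlds_data_error")
})

test_that("leave-one-out cross-validation behaves on separable and null data", {
  set.seed(56)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  Xsep <- cbind(y * 4 - 2 + rnorm(n, sd = 0.05),
                matrix(rnorm(n * 3), n, 3))
  m <- cross_validate(Xsep, y, ncomp = 2)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$error, 0)
  # definitional identity error = 1 - accuracy
  cm <- m$confusion
  expect_equal(m$error, 1 - (cm["tp"] + cm["tn"]) / n, ignore_attr = TRUE)

  set.seed(57)
  Xn <- matrix(rnorm(40 * 6), 40, 6)
  yn <- sample(rep(c(0, 1), 20))
  aucs <- replicate(5, {
    yp <- sample(yn)
    suppressWarnings(cross_validate(Xn, yp, ncomp = 2)$auc)
  })
  expect_gt(mean(aucs), 0.30)
  expect_lt(mean(aucs), 0.70)
})

test_that("ICC(A,1) matches the two-way ANOVA oracle", {
  expect_equal(icc_absolute(1:10, 1:10)$icc, 1, tolerance = 1e-10)
  a <- c(1, 2, 4, 6, 7); b <- c(1, 3, 4, 5, 8)
  r <- icc_absolute(a, b)
  expect_equal(r$icc, icc_aov_oracle(a, b), tolerance = 1e-10)
  expect_true(r$lower <= r$icc && r$icc <= r$upper)
  set.seed(58)
  x1 <- rnorm(200); x2 <- rnorm(200)
  expect_lt(abs(icc_absolute(x1, x2)$icc), 0.15)
  expect_error(icc_absolute(1:3, 1:3), class = "gaitlds_data_error")
  expect_error(icc_absolute(rep(1, 10), rep(1, 10)),
               class = "gaitlds_data_error")
})

test_that("group comparison is a two-sided Mann-Whitney test", {
  set.seed(59)
  g <- rep(c("faller", "nonfaller"), each = 10)
  same <- data.frame(f = rep(1:10, 2))
  r <- group_compare(same, g)
  expect_gt(r$p, 0.9)
  apart <- data.frame(f = c(rnorm(10), rnorm(10) + 50))
  expect_lt(group_compare(apart, g)$p, 1e-3)

  # U statistic equals the all-pairs concordance count
  x <- rnorm(10); y2 <- rnorm(10) + 0.5
  U <- sum(outer(x, y2, ">")) + 0.5 * sum(outer(x, y2, "=="))
  W <- suppressWarnings(wilcox.test(x, y2, exact = FALSE)$statistic)
  expect_equal(unname(W), U)
})
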