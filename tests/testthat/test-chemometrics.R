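test_that("PCA explains a line exactly and reconstructs at full rank", {
  t <- seq(-2, 2, length.out = 20)
  X <- cbind(t, 2 * t, -t) + 5
  p <- pca_fit(X, 2)
  expect_equal(p$explained[1], 1)

  set.seed(1)
  X <- matrix(rnorm(8 * 4), 8, 4)
  p <- pca_fit(X, 4)
  rec <- sweep(p$scores %*% t(p$loadings), 2, p$center, "+")
  expect_equal(rec, X, ignore_attr = TRUE)

  # explained fractions match the covariance eigendecomposition
  ev <- eigen(cov(X))$values
  expect_equal(p$explained, ev / sum(ev))
  expect_error(pca_fit(X, 9), "out of range")
})

test_that("NIPALS PLS recovers exact linear systems and matches OLS", {
  set.seed(2)
  X <- matrix(rnorm(30 * 5), 30, 5)
  b <- c(1, -2, 0.5, 3, -1)
  y <- X %*% b
  fit <- pls_fit(X, y, n_lv = 5)
  expect_equal(as.vector(fit$B), b, tolerance = 1e-8)
  expect_equal(unname(predict(fit, X)), unname(y), tolerance = 1e-8)

  # full-rank PLS equals least squares on noisy data
  y2 <- y + rnorm(30)
  fit2 <- pls_fit(X, y2, n_lv = 5)
  ols <- lm.fit(cbind(1, X), y2)$coefficients
  expect_equal(unname(predict(fit2, X)),
               unname(cbind(1, X) %*% ols), tolerance = 1e-8)

  # score vectors are mutually orthogonal
  G <- crossprod(fit2$T)
  expect_true(max(abs(G[upper.tri(G)])) < 1e-8)

  # single-component data: first LV captures all response variance
  s <- rnorm(30)
  fit3 <- pls_fit(outer(s, c(1, 2, 3)), 2 * s, n_lv = 1)
  expect_equal(unname(predict(fit3, outer(s, c(1, 2, 3)))[, 1]), 2 * s,
               tolerance = 1e-10)
  expect_error(pls_fit(X, rep(1, 30), 2), "zero-variance")
  expect_error(pls_fit(X, y, 0), "out of range")
})

test_that("NIPALS agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rnorm(25 * 8), 25, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  y <- X %*% rnorm(8) + rnorm(25, sd = 0.4)
  fit <- pls_fit(X, y, n_lv = 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  expect_equal(unname(predict(fit, X)),
               unname(as.matrix(predict(ref, X)$predict[, , 4])),
               tolerance = 1e-10)
})

test_that("PLS-DA separates clouds and is at chance on permuted labels", {
  cl <- two_clouds(12, sep = 8)
  fit <- plsda_fit(cl$X, cl$y, n_lv = 2)
  expect_equal(classification_accuracy(fit, cl$X, cl$y), 100)

  # permuted labels, larger n: accuracy near chance (50% for 2 classes)
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  y <- factor(rep(c("a", "b"), n / 2))
  fit0 <- plsda_fit(X, y, n_lv = 2)
  acc <- classification_accuracy(fit0, X, y)
  expect_lt(abs(acc - 50), 10)   # binomial expectation around chance

  expect_error(plsda_fit(cl$X, factor(rep("a", 24)), 2), "2 classes")
  expect_error(plsda_fit(cl$X[1:13, ], factor(c(rep("a", 12), "b")), 2),
               ">= 2 training samples")
})

test_that("cross-validation Q2/RMSECV match an explicit refit loop", {
  set.seed(5)
  X <- matrix(rnorm(21 * 4), 21, 4)
  y <- X %*% c(1, 2, -1, 0.5) + rnorm(21, sd = 0.5)
  cv <- cross_validate(X, y, n_lv = 3, folds = 7)
  # naive loop oracle
  fid <- (seq_len(21) - 1) %% 7 + 1
  press <- 0; tss <- 0
  for (f in 1:7) {
    hold <- fid == f
    fit <- pls_fit(X[!hold, ], y[!hold], n_lv = 3)
    pred <- predict(fit, X[hold, , drop = FALSE])
    press <- press + sum((y[hold] - pred)^2)
    tss <- tss + sum((y[hold] - mean(y[!hold]))^2)
  }
  expect_equal(cv$PRESS, press)
  expect_equal(cv$Q2, 1 - press / tss)
  expect_equal(cv$RMSECV, sqrt(press / 21))

  # perfect noiseless linear data
  y0 <- X %*% c(1, 2, -1, 0.5)
  cv0 <- cross_validate(X, y0, n_lv = 4, folds = 7)
  expect_equal(cv0$Q2, 1, tolerance = 1e-6)
  expect_lt(cv0$RMSECV, 1e-6)

  # pure-noise response: Q2 at or below zero
  set.seed(6)
  q2s <- replicate(5, {
    Xn <- matrix(rnorm(40 * 5), 40, 5)
    cross_validate(Xn, rnorm(40), n_lv = 3, folds = 7)$Q2
  })
  expect_lt(mean(q2s), 0)
})

test_that("Q2 never exceeds training R2 for the same configuration", {
  set.seed(7)
  for (rep in 1:4) {
    X <- matrix(rnorm(25 * 6), 25, 6)
    y <- X %*% rnorm(6) + rnorm(25, sd = runif(1, 0.2, 2))
    fit <- pls_fit(X, y, n_lv = 3)
    r2 <- 1 - sum((y - predict(fit, X))^2) / sum((y - mean(y))^2)
    q2 <- cross_validate(X, y, n_lv = 3, folds = 7)$Q2
    expect_lte(q2, r2)
  }
})

test_that("prediction metrics follow the RPD = SD/RMSEP identity", {
  # hand dataset of 5 reference/predicted pairs: spreadsheet arithmetic
  y <- c(1, 2, 3, 4, 5)
  yhat <- c(1.1, 1.8, 3.2, 4.1, 4.6)
  res <- y - yhat
  rmsep <- sqrt(mean(res^2))                         # 0.2449...
  fit <- list(n_lv = 1, B = matrix(1), intercept = 0, x_sd = 1,
              x_mean = 0, y_mean = 0, y_names = NULL,
              W = matrix(1), P = matrix(1), Q = matrix(1))
  class(fit) <- "pls_model"
  m <- evaluate(fit, matrix(yhat), y)
  expect_equal(m$RMSEP, rmsep)
  expect_equal(m$SD, sd(y))
  expect_equal(m$RPD, sd(y) / rmsep)
  expect_equal(m$R2p, 1 - sum(res^2) / sum((y - mean(y))^2))
  expect_equal(m$RPD * m$RMSEP, m$SD)                # identity

  # SD = 3, RMSEP = 1 -> RPD exactly 3, on the good/excellent boundary
  y2 <- c(-3, 0, 3)                        # sd(y2) = 3 exactly
  pred2 <- y2 + c(1, -1, 1) * sqrt(1)      # residuals +-1 -> RMSEP 1
  m2 <- evaluate(fit, matrix(pred2), y2)
  expect_equal(m2$SD, 3)
  expect_equal(m2$RMSEP, 1)
  expect_equal(m2$RPD, 3)
  expect_equal(m2$band, "good")

  # perfect prediction: infinite RPD flagged, not an error
  m3 <- evaluate(fit, matrix(y), y)
  expect_true(is.infinite(m3$RPD))
  expect_match(m3$band, "perfect")

  # zero reference SD: RPD undefined
  m4 <- evaluate(fit, matrix(c(1, 2, 3)), c(2, 2, 2))
  expect_true(is.na(m4$RPD))
  expect_equal(m4$band, "undefined")
})

test_that("VIP scores are normalised and find planted signals", {
  # identical feature copies: symmetry forces all VIPs to 1
  set.seed(8)
  s <- rnorm(20)
  X <- cbind(s, s, s, s)
  fit <- pls_fit(X, 3 * s + rnorm(20, sd = 0.1), n_lv = 1)
  expect_equal(unname(vip(fit)), rep(1, 4), tolerance = 1e-10)

  # sum VIP^2 = p for arbitrary models
  X2 <- matrix(rnorm(30 * 7), 30, 7)
  fit2 <- pls_fit(X2, X2 %*% rnorm(7) + rnorm(30), n_lv = 4)
  expect_equal(sum(vip(fit2)^2), 7, tolerance = 1e-10)

  # planted informative feature scores above 1, noise below
  set.seed(9)
  z <- rnorm(40)
  X3 <- cbind(z, matrix(rnorm(40 * 9), 40, 9))
  fit3 <- pls_fit(X3, 2 * z + rnorm(40, sd = 0.2), n_lv = 2)
  v <- vip(fit3)
  expect_gt(v[1], 1)
  expect_gt(v[1], max(v[-1]))
})

test_that("latent-variable selection finds planted ranks", {
  set.seed(10)
  T2 <- matrix(rnorm(40 * 2), 40, 2)
  X <- T2 %*% matrix(rnorm(2 * 10), 2, 10)
  y <- T2 %*% c(1, -2)
  # scanning past the true rank triggers the (expected) extraction warning
  sel <- suppressWarnings(select_latent_variables(X, y, max_lv = 6, folds = 7))
  expect_equal(sel$n_lv, 2L)

  # pure noise under the one-SE rule collapses to one component
  Xn <- matrix(rnorm(40 * 8), 40, 8)
  seln <- select_latent_variables(Xn, rnorm(40), max_lv = 6, folds = 7,
                                  one_se = TRUE)
  expect_equal(seln$n_lv, 1L)
})

test_that("permutation test validates real structure and flags null labels", {
  set.seed(11)
  cl <- two_clouds(10, sep = 6)
  pt <- permutation_test(cl$X, cl$y, n_lv = 2, n_perm = 30, seed = 1)
  expect_true(all(pt$correlation_axis >= 0 & pt$correlation_axis <= 1))
  expect_gt(pt$R2, max(pt$permuted_R2))
  expect_equal(pt$verdict, "no overfitting")

  # already-random labels: original statistic sits inside the permuted
  # distribution and the verdict flags overfitting risk
  yr <- factor(sample(rep(c("a", "b"), each = 10)))
  Xr <- matrix(rnorm(20 * 5), 20, 5)
  ptr <- permutation_test(Xr, yr, n_lv = 2, n_perm = 30, seed = 2)
  expect_lt(ptr$R2, max(ptr$permuted_R2) + 0.1)
  expect_equal(ptr$verdict, "overfitting risk")

  # intercepts are stable across seeds (Monte-Carlo tolerance)
  pt2 <- permutation_test(cl$X, cl$y, n_lv = 2, n_perm = 30, seed = 99)
  expect_equal(pt$intercept_R2, pt2$intercept_R2, tolerance = 0.15)
  expect_error(permutation_test(cl$X, cl$y, 2, n_perm = 5), ">= 10")
})
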