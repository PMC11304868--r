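#' Principal component analysis (mean-centered SVD)
#'
#' Thin wrapper around [stats::prcomp] returning scores, loadings and
#' explained-variance fractions (non-increasing, summing to <= 1 when
#' truncated at k components).
#'
#' @param X Samples x features matrix.
#' @param k Number of components, `<= min(n - 1, p)`.
#' @param scale Unit-variance scaling (default `FALSE`).
#' @return List with `scores` (n x k), `loadings` (p x k), `explained`
#'   (length-k fractions), `center`.
#' @export
pca_fit <- function(X, k, scale = FALSE) {
  X <- as.matrix(X)
  if (k < 1 || k > min(nrow(X) - 1, ncol(X))) stop("k out of range")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       center = pc$center)
}

# deterministic fold assignment
cv_folds <- function(n, folds, scheme = c("venetian", "contiguous", "random"),
                     seed = NULL) {
  scheme <- match.arg(scheme)
  if (folds > n) stop("folds must be <= n")
  switch(scheme,
         venetian = (seq_len(n) - 1L) %% folds + 1L,
         contiguous = ceiling(seq_len(n) * folds / n),
         random = {
           if (!is.null(seed)) set.seed(seed)
           sample((seq_len(n) - 1L) %% folds + 1L)
         })
}

#' Cross-validated Q2 and RMSECV for a PLS configuration
#'
#' k-fold cross-validation (default 7-fold, deterministic venetian-blind
#' assignment by sample order). `Q2 = 1 - PRESS/TSS` with the total sum of
#' squares taken about the training mean of each fold's complement;
#' `RMSECV = sqrt(PRESS / n)` (summed over responses).
#'
#' @param X,Y Data and response (vector or matrix; one-hot for PLS-DA).
#' @param n_lv Latent variables.
#' @param folds Number of folds (default 7).
#' @param scheme `"venetian"` (default), `"contiguous"` or `"random"`.
#' @param seed Seed for `scheme = "random"`.
#' @param scale Passed to [pls_fit].
#' @return List with `Q2`, `RMSECV`, `PRESS`, `TSS`, `folds`.
#' @export
cross_validate <- function(X, Y, n_lv, folds = 7, scheme = "venetian",
                           seed = NULL, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fid <- cv_folds(n, folds, scheme, seed)
  press <- 0; tss <- 0
  for (f in sort(unique(fid))) {
    hold <- fid == f
    fit <- pls_fit(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                   n_lv = min(n_lv, sum(!hold) - 1), scale = scale)
    pred <- predict(fit, X[hold, , drop = FALSE])
    press <- press + sum((Y[hold, , drop = FALSE] - pred)^2)
    mu <- colMeans(Y[!hold, , drop = FALSE])
    tss <- tss + sum(sweep(Y[hold, , drop = FALSE], 2, mu)^2)
  }
  list(Q2 = 1 - press / tss, RMSECV = sqrt(press / (n * ncol(Y))),
       PRESS = press, TSS = tss, folds = folds)
}

#' Choose the number of latent variables by cross-validated RMSECV
#'
#' Scans 1..`max_lv`, computing RMSECV for each count with one model fit per
#' fold (predictions truncated per component), and returns the minimiser; the
#' one-standard-error rule (smallest count within one SE of the minimum) is
#' available as a fallback.
#'
#' @param X,Y Data and response.
#' @param max_lv Largest component count scanned.
#' @param folds CV folds (default 7).
#' @param one_se Apply the one-SE rule (default `FALSE`).
#' @param scale Passed to [pls_fit].
#' @return List with `n_lv` (chosen), `rmsecv` (per count), `q2` (per count).
#' @export
select_latent_variables <- function(X, Y, max_lv, folds = 7, one_se = FALSE,
                                    scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (max_lv < 1) stop("max_lv must be >= 1")
  max_lv <- min(max_lv, n - ceiling(n / folds) - 1, ncol(X))
  fid <- cv_folds(n, folds, "venetian")
  press <- matrix(0, folds, max_lv)
  tss <- numeric(folds)
  for (f in sort(unique(fid))) {
    hold <- fid == f
    a_max <- min(max_lv, sum(!hold) - 1)
    fit <- pls_fit(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                   n_lv = a_max, scale = scale)
    for (a in seq_len(max_lv)) {
      pred <- predict(fit, X[hold, , drop = FALSE], ncomp = min(a, fit$n_lv))
      press[f, a] <- sum((Y[hold, , drop = FALSE] - pred)^2)
    }
    mu <- colMeans(Y[!hold, , drop = FALSE])
    tss[f] <- sum(sweep(Y[hold, , drop = FALSE], 2, mu)^2)
  }
  rmsecv <- sqrt(colSums(press) / (n * ncol(Y)))
  q2 <- 1 - colSums(press) / sum(tss)
  best <- which.min(rmsecv)
  if (one_se) {
    # SE of the fold-wise RMSECV at the minimiser
    fold_rmse <- sqrt(press[, best] / (tabulate(fid, folds) * ncol(Y)))
    se <- stats::sd(fold_rmse) / sqrt(folds)
    best <- which(rmsecv <= rmsecv[best] + se)[1]
  }
  list(n_lv = as.integer(best), rmsecv = rmsecv, q2 = q2)
}

#' Evaluate a fitted PLS model on a prediction set
#'
#' Per response: `RMSEP = sqrt(mean((y - yhat)^2))`; `R2p = 1 - SSE/SST`
#' with SST about the prediction-set mean; `SD` the (n-1) standard deviation
#' of the reference values; `RPD = SD / RMSEP` (Eq. RPD = SD/RMSEP), with
#' the usual interpretation bands (<1.4 poor, 1.4-3.0 good, >3.0 excellent).
#' A zero reference SD leaves RPD undefined (`NA`, band "undefined"); a zero
#' RMSEP is flagged infinite.
#'
#' @param model A fitted `pls_model`.
#' @param X_test,Y_test Prediction-set data and reference values.
#' @param ncomp Components used (default: all fitted).
#' @return `model_metrics` data.frame: one row per response with `response`,
#'   `R2p`, `RMSEP`, `SD`, `RPD`, `band`.
#' @export
evaluate <- function(model, X_test, Y_test, ncomp = model$n_lv) {
  Y_test <- as.matrix(Y_test)
  pred <- predict(model, X_test, ncomp = ncomp)
  out <- lapply(seq_len(ncol(Y_test)), function(j) {
    y <- Y_test[, j]; yh <- pred[, j]
    rmsep <- sqrt(mean((y - yh)^2))
    sdref <- stats::sd(y)
    sst <- sum((y - mean(y))^2)
    r2p <- if (sst > 0) 1 - sum((y - yh)^2) / sst else NA_real_
    rpd <- if (sdref == 0) NA_real_ else sdref / rmsep   # Inf when rmsep = 0
    band <- if (is.na(rpd)) "undefined"
            else if (is.infinite(rpd)) "excellent (perfect prediction)"
            else if (rpd < 1.4) "poor"
            else if (rpd <= 3.0) "good"
            else "excellent"
    data.frame(response = if (!is.null(colnames(Y_test))) colnames(Y_test)[j]
                          else paste0("Y", j),
               R2p = r2p, RMSEP = rmsep, SD = sdref, RPD = rpd, band = band)
  })
  out <- do.call(rbind, out)
  class(out) <- c("model_metrics", class(out))
  out
}

#' Training-set (calibration) metrics of a fitted PLS model
#'
#' @param model A fitted `pls_model`.
#' @param X,Y The calibration data the model was fitted on.
#' @param ncomp Components used.
#' @return data.frame with per-response `R2c` and `RMSEC`.
#' @export
calibration_metrics <- function(model, X, Y, ncomp = model$n_lv) {
  Y <- as.matrix(Y)
  pred <- predict(model, X, ncomp = ncomp)
  do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]; yh <- pred[, j]
    data.frame(response = if (!is.null(colnames(Y))) colnames(Y)[j]
                          else paste0("Y", j),
               R2c = 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
               RMSEC = sqrt(mean((y - yh)^2)))
  }))
}

#' Classification accuracy of a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param X Feature matrix.
#' @param labels True labels.
#' @param ncomp Components used.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(model, X, labels, ncomp = model$n_lv) {
  pred <- predict_class(model, X, ncomp = ncomp)
  100 * mean(as.character(pred) == as.character(labels))
}

#' Label-permutation test for a PLS-DA model
#'
#' Refits the PLS-DA on `n_perm` random label permutations, recording the
#' training R2 (explained indicator variance), the cross-validated Q2, and
#' the absolute correlation between the permuted and original one-hot label
#' matrices. Straight lines are fitted by OLS through the (correlation,
#' statistic) pairs including the unpermuted model at correlation 1; the
#' reported intercepts are the validation criterion: no overfitting is
#' declared when the original R2/Q2 exceed every permuted value and the R2
#' intercept is below `r2_bound` (default 0.4) with a negative Q2 intercept.
#'
#' @param X Feature matrix.
#' @param labels Class labels.
#' @param n_lv Latent variables (fixed across refits).
#' @param n_perm Number of permutations (default 200, >= 10).
#' @param seed Seed for the permutations.
#' @param folds CV folds for Q2 (default 7).
#' @param r2_bound Intercept bound for the R2 line (default 0.4).
#' @param scale Passed to [pls_fit].
#' @return Object of class `permutation_result`: `R2`, `Q2` (originals),
#'   `permuted_R2`, `permuted_Q2`, `correlation_axis`, `intercept_R2`,
#'   `intercept_Q2`, `verdict`.
#' @export
permutation_test <- function(X, labels, n_lv, n_perm = 200, seed = NULL,
                             folds = 7, r2_bound = 0.4, scale = FALSE) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  X <- as.matrix(X)
  labels <- factor(labels)
  Y <- one_hot(labels)
  n <- nrow(X)
  fit <- pls_fit(X, Y, n_lv = n_lv, scale = scale)
  pred <- predict(fit, X)
  r2_orig <- 1 - sum((Y - pred)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
  q2_orig <- cross_validate(X, Y, n_lv = n_lv, folds = folds, scale = scale)$Q2
  if (!is.null(seed)) set.seed(seed)
  perm_r2 <- numeric(n_perm); perm_q2 <- numeric(n_perm)
  corr <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Yp <- Y[idx, , drop = FALSE]
    corr[b] <- abs(stats::cor(as.vector(Yp), as.vector(Y)))
    fb <- pls_fit(X, Yp, n_lv = n_lv, scale = scale)
    pb <- predict(fb, X)
    perm_r2[b] <- 1 - sum((Yp - pb)^2) / sum(sweep(Yp, 2, colMeans(Yp))^2)
    perm_q2[b] <- cross_validate(X, Yp, n_lv = n_lv, folds = folds,
                                 scale = scale)$Q2
  }
  cx <- c(corr, 1)
  ir2 <- unname(stats::coef(stats::lm(c(perm_r2, r2_orig) ~ cx))[1])
  iq2 <- unname(stats::coef(stats::lm(c(perm_q2, q2_orig) ~ cx))[1])
  verdict <- if (r2_orig > max(perm_r2) && q2_orig > max(perm_q2) &&
                 ir2 < r2_bound && iq2 < 0) "no overfitting"
             else "overfitting risk"
  structure(list(R2 = r2_orig, Q2 = q2_orig,
                 permuted_R2 = perm_r2, permuted_Q2 = perm_q2,
                 correlation_axis = corr,
                 intercept_R2 = ir2, intercept_Q2 = iq2,
                 n_perm = n_perm, verdict = verdict),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%d permutations)\n", x$n_perm))
  cat(sprintf("  original R2 = %.3f, Q2 = %.3f\n", x$R2, x$Q2))
  cat(sprintf("  intercepts: R2 = %.3f, Q2 = %.3f -> %s\n",
              x$intercept_R2, x$intercept_Q2, x$verdict))
  invisible(x)
}
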