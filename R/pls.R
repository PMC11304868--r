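#' Fit a partial least squares model by NIPALS
#'
#' NIPALS with deflation of both blocks. X is mean-centered (optionally
#' unit-variance scaled, which is common for concentration responses but
#' usually off for raw spectra); Y is mean-centered. Regression coefficients
#' are assembled as `B = W (P'W)^{-1} Q'` on the preprocessed scale and
#' back-transformed, so `predict()` is `intercept + X %*% B`.
#'
#' @param X Samples x features matrix.
#' @param Y Response vector or samples x responses matrix.
#' @param n_lv Number of latent variables, `<= min(n - 1, p)`.
#' @param scale Unit-variance scale X (default `FALSE`).
#' @param tol NIPALS convergence tolerance on the score vector (1e-10).
#' @param max_iter Maximum NIPALS inner iterations per component (500).
#' @return Object of class `pls_model` with weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, scores `T`, coefficients `B` (original X scale),
#'   `intercept`, `ssy` (Y variance captured per component), centering/
#'   scaling vectors, `n_lv`, `mode = "regression"`.
#' @export
pls_fit <- function(X, Y, n_lv, scale = FALSE, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop("n_lv out of range: must be in [1, min(n - 1, p)]")
  x_mean <- colMeans(X)
  x_sd <- rep(1, p)
  Xc <- sweep(X, 2, x_mean)
  if (scale) {
    x_sd <- apply(X, 2, stats::sd)
    x_sd[x_sd == 0] <- 1
    Xc <- sweep(Xc, 2, x_sd, "/")
  }
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2, y_mean)
  if (all(abs(Yc) < .Machine$double.eps * 100))
    stop("zero-variance response")
  W <- matrix(0, p, n_lv, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv); TT <- matrix(0, n, n_lv)
  ssy <- numeric(n_lv)
  a <- 0
  for (comp in seq_len(n_lv)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var)), drop = FALSE]
    if (sum(u^2) < 1e-14) break
    t_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      qq <- crossprod(Yc, tt) / sum(tt^2)
      if (q == 1) break
      u <- Yc %*% qq / sum(qq^2)
      if (!is.null(t_old) &&
          sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    tt2 <- sum(tt^2)
    if (tt2 < 1e-14) break
    pp <- crossprod(Xc, tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, qq)
    a <- comp
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; TT[, a] <- tt
    ssy[a] <- tt2 * sum(qq^2)
  }
  if (a == 0) stop("no latent variable could be extracted")
  if (a < n_lv) {
    warning("only ", a, " latent variable(s) extractable; n_lv reduced")
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[, seq_len(a), drop = FALSE]; TT <- TT[, seq_len(a), drop = FALSE]
    ssy <- ssy[seq_len(a)]
  }
  model <- structure(list(n_lv = a, W = W, P = P, Q = Q, T = TT, ssy = ssy,
                          x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                          scale = scale, mode = "regression",
                          y_names = colnames(Y)),
                     class = "pls_model")
  cf <- pls_coefficients(model, a)
  model$B <- cf$B
  model$intercept <- cf$intercept
  model
}

# coefficients using the first `ncomp` components, on the original X scale
pls_coefficients <- function(model, ncomp = model$n_lv) {
  idx <- seq_len(ncomp)
  W <- model$W[, idx, drop = FALSE]
  P <- model$P[, idx, drop = FALSE]
  Q <- model$Q[, idx, drop = FALSE]
  Bstar <- W %*% solve(crossprod(P, W), t(Q))
  B <- Bstar / model$x_sd
  intercept <- model$y_mean - as.vector(crossprod(B, model$x_mean))
  list(B = B, intercept = intercept)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Samples x features matrix.
#' @param ncomp Number of components used (default: all fitted).
#' @param ... Unused.
#' @return Predicted response matrix (samples x responses).
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  cf <- if (ncomp == object$n_lv && !is.null(object$B))
    list(B = object$B, intercept = object$intercept)
  else pls_coefficients(object, ncomp)
  out <- sweep(newdata %*% cf$B, 2, cf$intercept, "+")
  colnames(out) <- object$y_names
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model (%s): %d latent variable(s), %d feature(s), %d response(s)\n",
              x$mode, x$n_lv, nrow(x$W), nrow(x$Q)))
  invisible(x)
}

#' Fit a PLS-DA classifier
#'
#' One-hot encodes the class labels and fits a PLS regression on the
#' indicator matrix; the predicted class is the arg-max of the predicted
#' indicator columns (ties broken toward the first class in level order,
#' with a warning).
#'
#' @param X Samples x features matrix.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @param n_lv Number of latent variables.
#' @param scale Unit-variance scale X (default `FALSE`, usual for spectra).
#' @return A `plsda_model` (inherits `pls_model`) with a `classes` field.
#' @export
plsda_fit <- function(X, labels, n_lv, scale = FALSE) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2))
    stop("each class needs >= 2 training samples; missing/rare class: ",
         paste(names(which(table(labels) < 2)), collapse = ", "))
  Y <- one_hot(labels)
  model <- pls_fit(X, Y, n_lv = n_lv, scale = scale)
  model$classes <- levels(labels)
  model$mode <- "discriminant"
  class(model) <- c("plsda_model", class(model))
  model
}

#' One-hot indicator matrix for class labels
#'
#' The indicator encoding used by PLS-DA; useful directly when
#' cross-validating a discriminant configuration with [cross_validate] or
#' [select_latent_variables].
#'
#' @param labels Class labels (coerced to factor).
#' @return n x nlevels 0/1 matrix with class names as columns.
#' @export
one_hot <- function(labels) {
  labels <- factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Predict classes from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Samples x features matrix.
#' @param ncomp Components used (default: all fitted).
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict_class <- function(object, newdata, ncomp = object$n_lv, ...) {
  stopifnot(inherits(object, "plsda_model"))
  scores <- predict(object, newdata, ncomp = ncomp)
  ties <- apply(scores, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    warning(sum(ties), " tie(s) in class scores broken by class order")
  idx <- apply(scores, 1, which.max)
  factor(object$classes[idx], levels = object$classes)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` where `ssy_a` is the
#' Y variance captured by component a and the weight vectors are unit
#' length. The mean of squared VIPs is always 1 (`sum VIP^2 = p`).
#'
#' @param model A fitted `pls_model` with >= 1 component.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("zero explained Y variance; VIP undefined")
  W2 <- model$W^2                       # columns are unit-norm weights
  p <- nrow(W2)
  v <- sqrt(p * as.vector(W2 %*% ssy) / sum(ssy))
  names(v) <- rownames(model$W)
  v
}
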