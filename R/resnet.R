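# A compact 12-layer residual CNN for correlation-map images, implemented
# directly on BLAS matrix products (im2col convolutions). Activation layout:
# one column per sample, elements ordered pixel-fastest (h, then w), channel
# slowest, which makes padding/indexing a single precomputed integer lookup.

conv_make <- function(in_shape, k, stride, pad, out_ch) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  kkC <- k * k * C
  # index of each (kh, kw, c) x (ho, wo) patch element in the padded vector
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  hh <- outer(kh, (ho - 1L) * stride, "+")          # kkC x HoWo
  ww <- outer(kw, (wo - 1L) * stride, "+")
  idx <- hh + (ww - 1L) * Hp + (cc - 1L) * (Hp * Wp)
  # position of unpadded pixels inside the padded vector
  h0 <- rep(seq_len(H), times = W * C)
  w0 <- rep(rep(seq_len(W), each = H), times = C)
  c0 <- rep(seq_len(C), each = H * W)
  pad_idx <- (h0 + pad) + (w0 + pad - 1L) * Hp + (c0 - 1L) * (Hp * Wp)
  Wmat <- matrix(stats::rnorm(out_ch * kkC, sd = sqrt(2 / kkC)), out_ch, kkC)
  list(type = "conv", in_shape = in_shape, out_shape = c(Ho, Wo, out_ch),
       k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, C = C, kkC = kkC, HoWo = Ho * Wo,
       idx = as.integer(idx), pad_idx = as.integer(pad_idx),
       W = Wmat, b = numeric(out_ch))
}

conv_forward <- function(ly, A) {
  N <- ncol(A)
  if (ly$pad > 0) {
    P <- matrix(0, ly$Hp * ly$Wp * ly$C, N)
    P[ly$pad_idx, ] <- A
  } else P <- A
  Xc <- P[ly$idx, , drop = FALSE]                    # (kkC*HoWo) x N
  dim(Xc) <- c(ly$kkC, ly$HoWo * N)
  Y <- ly$W %*% Xc + ly$b                            # F x (HoWo*N)
  Fch <- ly$out_shape[3]
  dim(Y) <- c(Fch, ly$HoWo, N)
  Y <- aperm(Y, c(2, 1, 3))
  dim(Y) <- c(ly$HoWo * Fch, N)
  list(out = Y, Xc = Xc, N = N)
}

conv_backward <- function(ly, dOut, cache, need_dA = TRUE) {
  N <- cache$N; Fch <- ly$out_shape[3]
  dim(dOut) <- c(ly$HoWo, Fch, N)
  dY <- aperm(dOut, c(2, 1, 3))
  dim(dY) <- c(Fch, ly$HoWo * N)
  dW <- tcrossprod(dY, cache$Xc)
  db <- rowSums(dY)
  dA <- NULL
  if (need_dA) {
    dXc <- crossprod(ly$W, dY)                       # kkC x (HoWo*N)
    len <- ly$Hp * ly$Wp * ly$C
    full_idx <- rep(ly$idx, times = N) +
      rep((seq_len(N) - 1L) * len, each = length(ly$idx))
    agg <- rowsum(as.vector(dXc), group = full_idx)
    dP <- numeric(len * N)
    dP[as.integer(rownames(agg))] <- agg
    dim(dP) <- c(len, N)
    dA <- dP[ly$pad_idx, , drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

bn_make <- function(n_pix, C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", n_pix = n_pix, C = C, eps = eps, momentum = momentum,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C))
}

# channel index expansion for an (n_pix*C) x N activation
bn_expand <- function(ly, v) rep(v, each = ly$n_pix)

bn_forward <- function(ly, A, train = TRUE) {
  N <- ncol(A)
  dim(A) <- c(ly$n_pix, ly$C, N)
  if (train) {
    mu <- apply(A, 2, mean)
    va <- apply(A, 2, function(x) mean((x - mean(x))^2))
  } else {
    mu <- ly$rmean; va <- ly$rvar
  }
  ivar <- 1 / sqrt(va + ly$eps)
  xhat <- sweep(sweep(A, 2, mu), 2, ivar, "*")
  Y <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  dim(Y) <- c(ly$n_pix * ly$C, N)
  dim(xhat) <- c(ly$n_pix * ly$C, N)
  list(out = Y, xhat = xhat, ivar = ivar, mu = mu, va = va, N = N)
}

bn_backward <- function(ly, dOut, cache) {
  N <- cache$N; M <- ly$n_pix * N
  dim(dOut) <- c(ly$n_pix, ly$C, N)
  xhat <- cache$xhat
  dim(xhat) <- c(ly$n_pix, ly$C, N)
  dgamma <- apply(dOut * xhat, 2, sum)
  dbeta <- apply(dOut, 2, sum)
  coef <- ly$gamma * cache$ivar / M
  dx <- sweep(M * dOut, 2, dbeta) -
    sweep(xhat, 2, dgamma, "*")
  dx <- sweep(dx, 2, coef, "*")
  dim(dx) <- c(ly$n_pix * ly$C, N)
  list(dA = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_update_running <- function(ly, cache) {
  m <- ly$momentum
  ly$rmean <- (1 - m) * ly$rmean + m * cache$mu
  ly$rvar <- (1 - m) * ly$rvar + m * cache$va
  ly
}

#' Build the 12-layer residual CNN
#'
#' Architecture (weight layers counted in brackets): a strided stem
#' convolution [1] with batch normalisation and ReLU; a convolutional
#' residual block (projection shortcut, downsampling) [3]; an identity
#' residual block [2]; a second convolutional block [3]; a second identity
#' block [2]; global average pooling, flatten, and a fully connected output
#' layer [1] -- twelve learnable-weight layers in total. Identity blocks
#' preserve dimensionality (pure skip connection); convolutional blocks use
#' a 1x1 projection shortcut where dimensions change.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param image_edge Input edge in pixels; must be divisible by 16 (the
#'   network's total downsampling factor).
#' @param channels Widths of the three stages (default `c(8, 16, 32)`).
#' @param seed Seed for the weight initialisation.
#' @return Object of class `resnet_model` (list of layers + geometry).
#' @export
build_resnet <- function(n_classes, image_edge = 128, channels = c(8, 16, 32),
                         seed = 1) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (image_edge %% 16 != 0)
    stop("image_edge must be divisible by 16 (total downsampling factor)")
  set.seed(seed)
  e1 <- image_edge / 4; e2 <- e1 / 2; e3 <- e2 / 2
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  L <- list()
  L$stem_conv <- conv_make(c(image_edge, image_edge, 3), 5, 4, 2, c1)
  L$stem_bn <- bn_make(e1 * e1, c1)
  L$cb1_a_conv <- conv_make(c(e1, e1, c1), 3, 2, 1, c2)
  L$cb1_a_bn <- bn_make(e2 * e2, c2)
  L$cb1_b_conv <- conv_make(c(e2, e2, c2), 3, 1, 1, c2)
  L$cb1_b_bn <- bn_make(e2 * e2, c2)
  L$cb1_s_conv <- conv_make(c(e1, e1, c1), 1, 2, 0, c2)
  L$cb1_s_bn <- bn_make(e2 * e2, c2)
  L$ib1_a_conv <- conv_make(c(e2, e2, c2), 3, 1, 1, c2)
  L$ib1_a_bn <- bn_make(e2 * e2, c2)
  L$ib1_b_conv <- conv_make(c(e2, e2, c2), 3, 1, 1, c2)
  L$ib1_b_bn <- bn_make(e2 * e2, c2)
  L$cb2_a_conv <- conv_make(c(e2, e2, c2), 3, 2, 1, c3)
  L$cb2_a_bn <- bn_make(e3 * e3, c3)
  L$cb2_b_conv <- conv_make(c(e3, e3, c3), 3, 1, 1, c3)
  L$cb2_b_bn <- bn_make(e3 * e3, c3)
  L$cb2_s_conv <- conv_make(c(e2, e2, c2), 1, 2, 0, c3)
  L$cb2_s_bn <- bn_make(e3 * e3, c3)
  L$ib2_a_conv <- conv_make(c(e3, e3, c3), 3, 1, 1, c3)
  L$ib2_a_bn <- bn_make(e3 * e3, c3)
  L$ib2_b_conv <- conv_make(c(e3, e3, c3), 3, 1, 1, c3)
  L$ib2_b_bn <- bn_make(e3 * e3, c3)
  L$fc <- list(type = "fc",
               W = matrix(stats::rnorm(n_classes * c3, sd = sqrt(2 / c3)),
                          n_classes, c3),
               b = numeric(n_classes))
  structure(list(layers = L, n_classes = n_classes, image_edge = image_edge,
                 channels = channels, gap_pix = e3 * e3, seed = seed),
            class = "resnet_model")
}

#' @export
print.resnet_model <- function(x, ...) {
  n_w <- sum(vapply(x$layers, function(l)
    if (l$type %in% c("conv", "fc")) 1L else 0L, 0L))
  cat(sprintf("resnet_model: %d weight layers, input %dx%dx3, %d classes, stage widths %s\n",
              n_w, x$image_edge, x$image_edge, x$n_classes,
              paste(x$channels, collapse = "/")))
  invisible(x)
}

# forward pass; returns logits (classes x N) and caches when train = TRUE
resnet_forward <- function(model, A, train = TRUE) {
  L <- model$layers
  cc <- list()
  unit <- function(conv_nm, bn_nm, A, relu = TRUE) {
    cv <- conv_forward(L[[conv_nm]], A)
    bn <- bn_forward(L[[bn_nm]], cv$out, train = train)
    out <- bn$out
    mask <- NULL
    if (relu) { mask <- out > 0; out <- out * mask }
    cc[[conv_nm]] <<- cv; cc[[bn_nm]] <<- bn
    cc[[paste0(bn_nm, "_mask")]] <<- mask
    out
  }
  a0 <- unit("stem_conv", "stem_bn", A)
  # convolutional block 1
  m <- unit("cb1_a_conv", "cb1_a_bn", a0)
  m <- unit("cb1_b_conv", "cb1_b_bn", m, relu = FALSE)
  s <- unit("cb1_s_conv", "cb1_s_bn", a0, relu = FALSE)
  a1 <- m + s; mask1 <- a1 > 0; a1 <- a1 * mask1; cc$mask1 <- mask1
  # identity block 1
  m <- unit("ib1_a_conv", "ib1_a_bn", a1)
  m <- unit("ib1_b_conv", "ib1_b_bn", m, relu = FALSE)
  a2 <- m + a1; mask2 <- a2 > 0; a2 <- a2 * mask2; cc$mask2 <- mask2
  # convolutional block 2
  m <- unit("cb2_a_conv", "cb2_a_bn", a2)
  m <- unit("cb2_b_conv", "cb2_b_bn", m, relu = FALSE)
  s <- unit("cb2_s_conv", "cb2_s_bn", a2, relu = FALSE)
  a3 <- m + s; mask3 <- a3 > 0; a3 <- a3 * mask3; cc$mask3 <- mask3
  # identity block 2
  m <- unit("ib2_a_conv", "ib2_a_bn", a3)
  m <- unit("ib2_b_conv", "ib2_b_bn", m, relu = FALSE)
  a4 <- m + a3; mask4 <- a4 > 0; a4 <- a4 * mask4; cc$mask4 <- mask4
  # global average pooling + fc
  N <- ncol(a4)
  gp <- a4; dim(gp) <- c(model$gap_pix, model$channels[3] * N)
  feat <- colMeans(gp); dim(feat) <- c(model$channels[3], N)
  logits <- L$fc$W %*% feat + L$fc$b
  cc$feat <- feat
  list(logits = logits, cache = if (train) cc else NULL)
}

# backward pass; returns named list of gradients per layer
resnet_backward <- function(model, dlogits, cache) {
  L <- model$layers
  gr <- list()
  dfeat <- crossprod(L$fc$W, dlogits)
  gr$fc <- list(dW = tcrossprod(dlogits, cache$feat), db = rowSums(dlogits))
  N <- ncol(dlogits)
  da4 <- matrix(rep(dfeat / model$gap_pix, each = model$gap_pix),
                model$gap_pix * model$channels[3], N)
  back_unit <- function(conv_nm, bn_nm, d, need_dA = TRUE, relu = TRUE) {
    if (relu) d <- d * cache[[paste0(bn_nm, "_mask")]]
    bb <- bn_backward(L[[bn_nm]], d, cache[[bn_nm]])
    cb <- conv_backward(L[[conv_nm]], bb$dA, cache[[conv_nm]], need_dA)
    gr[[bn_nm]] <<- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
    gr[[conv_nm]] <<- list(dW = cb$dW, db = cb$db)
    cb$dA
  }
  # identity block 2
  d <- da4 * cache$mask4
  dm <- back_unit("ib2_b_conv", "ib2_b_bn", d, relu = FALSE)
  dm <- back_unit("ib2_a_conv", "ib2_a_bn", dm)
  da3 <- d + dm
  # convolutional block 2
  d <- da3 * cache$mask3
  dm <- back_unit("cb2_b_conv", "cb2_b_bn", d, relu = FALSE)
  dm <- back_unit("cb2_a_conv", "cb2_a_bn", dm)
  ds <- back_unit("cb2_s_conv", "cb2_s_bn", d, relu = FALSE)
  da2 <- dm + ds
  # identity block 1
  d <- da2 * cache$mask2
  dm <- back_unit("ib1_b_conv", "ib1_b_bn", d, relu = FALSE)
  dm <- back_unit("ib1_a_conv", "ib1_a_bn", dm)
  da1 <- d + dm
  # convolutional block 1
  d <- da1 * cache$mask1
  dm <- back_unit("cb1_b_conv", "cb1_b_bn", d, relu = FALSE)
  dm <- back_unit("cb1_a_conv", "cb1_a_bn", dm)
  ds <- back_unit("cb1_s_conv", "cb1_s_bn", d, relu = FALSE)
  da0 <- dm + ds
  # stem (no input gradient needed)
  back_unit("stem_conv", "stem_bn", da0, need_dA = FALSE)
  gr
}

softmax_ce <- function(logits, y_idx) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  pr <- sweep(ez, 2, colSums(ez), "/")
  N <- ncol(pr)
  loss <- -mean(log(pr[cbind(y_idx, seq_len(N))] + 1e-12))
  dlog <- pr
  dlog[cbind(y_idx, seq_len(N))] <- dlog[cbind(y_idx, seq_len(N))] - 1
  list(loss = loss, dlogits = dlog / N, prob = pr)
}

images_to_batch <- function(images, idx) {
  n <- length(idx)
  H <- dim(images)[2]
  A <- matrix(0, H * H * 3, n)
  for (i in seq_len(n)) A[, i] <- as.vector(images[idx[i], , , ])
  A
}

#' Classify images with a (trained) residual CNN
#'
#' Uses batch-normalisation running statistics (inference mode).
#'
#' @param model A `resnet_model`.
#' @param images Array n x edge x edge x 3.
#' @param classes Optional class labels to map predictions onto.
#' @param batch_size Evaluation batch size (default 16).
#' @return Integer class indices, or a factor if `classes` is given.
#' @export
predict_resnet <- function(model, images, classes = NULL, batch_size = 16) {
  n <- dim(images)[1]
  out <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    A <- images_to_batch(images, idx)
    lg <- resnet_forward(model, A, train = FALSE)$logits
    out[idx] <- apply(lg, 2, which.max)
  }
  if (!is.null(classes)) factor(classes[out], levels = classes) else out
}

#' Train the residual CNN with SGD
#'
#' Plain stochastic gradient descent on the softmax cross-entropy with the
#' stated learning rate and weight decay (decay applied to convolution and
#' fully-connected weights only). Per-epoch train/test accuracy and mean
#' training loss are recorded; training can stop early once the test
#' accuracy reaches `early_stop_acc` percent.
#'
#' @param model A `resnet_model` from [build_resnet].
#' @param images Array n x edge x edge x 3 (values in [0, 1]).
#' @param labels Class label per image.
#' @param split A `split_result` giving train/test indices.
#' @param epochs Maximum epochs (default 30).
#' @param batch_size Minibatch size (default 8).
#' @param lr Learning rate (default 0.01).
#' @param weight_decay L2 coefficient (default 1e-4).
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param seed Seed for shuffling (default 1).
#' @param early_stop_acc Stop once test accuracy (%) reaches this value
#'   (default `NULL`: run all epochs).
#' @param verbose Print per-epoch progress (default `FALSE`).
#' @return List: `model` (trained), `trace` (data.frame epoch, loss,
#'   train_acc, test_acc), `classes`.
#' @export
resnet_train <- function(model, images, labels, split, epochs = 30,
                         batch_size = 8, lr = 0.01, weight_decay = 1e-4,
                         momentum = 0, seed = 1, early_stop_acc = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(model, "resnet_model"), inherits(split, "split_result"))
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) != model$n_classes)
    stop("label classes do not match the model's n_classes")
  tr <- split$train_idx; te <- split$test_idx
  if (any(table(labels[tr]) < 2))
    stop("class missing (or singleton) in training split")
  y <- as.integer(labels)
  set.seed(seed)
  vel <- NULL
  if (momentum > 0) vel <- lapply(model$layers, function(l)
    if (l$type %in% c("conv", "fc")) list(W = 0 * l$W, b = 0 * l$b) else NULL)
  trace <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    losses <- c()
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, length(ord))]
      A <- images_to_batch(images, idx)
      fw <- resnet_forward(model, A, train = TRUE)
      sc <- softmax_ce(fw$logits, y[idx])
      losses <- c(losses, sc$loss)
      gr <- resnet_backward(model, sc$dlogits, fw$cache)
      for (nm in names(model$layers)) {
        l <- model$layers[[nm]]
        if (l$type == "bn") {
          model$layers[[nm]] <- bn_update_running(l, fw$cache[[nm]])
          g <- gr[[nm]]
          model$layers[[nm]]$gamma <- model$layers[[nm]]$gamma - lr * g$dgamma
          model$layers[[nm]]$beta <- model$layers[[nm]]$beta - lr * g$dbeta
        } else {
          g <- gr[[nm]]
          dW <- g$dW + weight_decay * l$W
          if (momentum > 0) {
            vel[[nm]]$W <- momentum * vel[[nm]]$W - lr * dW
            vel[[nm]]$b <- momentum * vel[[nm]]$b - lr * g$db
            model$layers[[nm]]$W <- l$W + vel[[nm]]$W
            model$layers[[nm]]$b <- l$b + vel[[nm]]$b
          } else {
            model$layers[[nm]]$W <- l$W - lr * dW
            model$layers[[nm]]$b <- l$b - lr * g$db
          }
        }
      }
    }
    acc_tr <- 100 * mean(predict_resnet(model, images[tr, , , , drop = FALSE]) ==
                           y[tr])
    acc_te <- 100 * mean(predict_resnet(model, images[te, , , , drop = FALSE]) ==
                           y[te])
    trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                     train_acc = acc_tr, test_acc = acc_te))
    if (verbose)
      message(sprintf("epoch %2d: loss %.4f train %.1f%% test %.1f%%",
                      ep, mean(losses), acc_tr, acc_te))
    if (!is.null(early_stop_acc) && acc_te >= early_stop_acc &&
        acc_tr >= early_stop_acc) break
  }
  list(model = model, trace = trace, classes = classes)
}
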