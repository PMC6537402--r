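# A small 1-D convolutional network over the 33-position x 10-channel CDR
# feature matrix: Conv - LeakyReLU - MaxPool units, fully connected hidden
# layers with LeakyReLU, 2-way softmax output, Adam optimization.
# Written in plain matrix algebra (im2col convolutions) so the whole model
# is inspectable and gradient-checkable.

.leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
.dleaky <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# reshape n x (P*C) position-major rows into an (n, P, C) array
.to_array <- function(x, positions, channels) {
  aperm(array(x, dim = c(nrow(x), channels, positions)), c(1, 3, 2))
}

.conv_forward <- function(X, W, b, w) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - w + 1
  M <- matrix(0, n * Lout, w * C)
  for (o in seq_len(w)) {
    M[, ((o - 1) * C + 1):(o * C)] <-
      matrix(X[, o:(o + Lout - 1), , drop = FALSE], n * Lout, C)
  }
  Z <- sweep(M %*% W, 2, b, "+")
  list(A = array(Z, c(n, Lout, ncol(W))), M = M, n = n, Lout = Lout,
       C = C, L = L)
}

.conv_backward <- function(cache, W, w, dA) {
  n <- cache$n; Lout <- cache$Lout; C <- cache$C; L <- cache$L
  K <- ncol(W)
  dZ <- matrix(dA, n * Lout, K)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dX <- array(0, c(n, L, C))
  for (o in seq_len(w)) {
    dX[, o:(o + Lout - 1), ] <- dX[, o:(o + Lout - 1), ] +
      array(dM[, ((o - 1) * C + 1):(o * C)], c(n, Lout, C))
  }
  list(dX = dX, dW = dW, db = db)
}

.pool_forward <- function(A, p) {
  d <- dim(A); n <- d[1]; L <- d[2]; K <- d[3]
  Lp <- L %/% p
  .assert(Lp >= 1, "pooling window larger than feature length")
  base <- (seq_len(Lp) - 1) * p
  P <- A[, base + 1, , drop = FALSE]
  argm <- array(1L, dim(P))
  if (p > 1) {
    for (o in 2:p) {
      cand <- A[, base + o, , drop = FALSE]
      upd <- cand > P
      P[upd] <- cand[upd]
      argm[upd] <- o
    }
  }
  list(P = P, argm = argm, p = p, L = L, Lp = Lp)
}

.pool_backward <- function(cache, dP) {
  d <- dim(dP); n <- d[1]; Lp <- d[2]; K <- d[3]
  dA <- array(0, c(n, cache$L, K))
  base <- (seq_len(Lp) - 1) * cache$p
  for (o in seq_len(cache$p)) {
    tmp <- array(0, dim(dP))
    sel <- cache$argm == o
    tmp[sel] <- dP[sel]
    dA[, base + o, ] <- dA[, base + o, ] + tmp
  }
  dA
}

.init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# build parameter list for a hyperparameter setting
.convnet_init <- function(hyper, positions = 33, channels = 10) {
  layers <- list()
  L <- positions; C <- channels
  for (l in seq_len(hyper$n_conv_layers)) {
    w <- hyper$kernel_width
    .assert(L - w + 1 >= hyper$pool_width, "feature map too short")
    layers[[length(layers) + 1]] <- list(
      type = "conv", w = w, p = hyper$pool_width,
      W = .init_mat(w * C, hyper$n_kernels), b = rep(0, hyper$n_kernels)
    )
    L <- (L - w + 1) %/% hyper$pool_width
    C <- hyper$n_kernels
  }
  nin <- L * C
  for (l in seq_len(hyper$n_fc_layers)) {
    layers[[length(layers) + 1]] <- list(
      type = "fc", W = .init_mat(nin, hyper$fc_units), b = rep(0, hyper$fc_units)
    )
    nin <- hyper$fc_units
  }
  layers[[length(layers) + 1]] <- list(
    type = "out", W = .init_mat(nin, 2), b = rep(0, 2)
  )
  layers
}

# forward pass; returns probabilities and (optionally) caches for backprop
.convnet_forward <- function(layers, X3, keep_prob = 1, train = FALSE) {
  caches <- vector("list", length(layers))
  A <- X3
  flat <- NULL
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      cf <- .conv_forward(A, lay$W, lay$b, lay$w)
      act <- .leaky(cf$A)
      pf <- .pool_forward(act, lay$p)
      caches[[li]] <- list(conv = cf, pre = cf$A, pool = pf)
      A <- pf$P
    } else {
      if (is.null(flat)) {
        d <- dim(A)
        flat <- matrix(A, d[1], d[2] * d[3])
      }
      Z <- sweep(flat %*% lay$W, 2, lay$b, "+")
      if (lay$type == "fc") {
        H <- .leaky(Z)
        mask <- NULL
        if (train && keep_prob < 1) {
          mask <- matrix(stats::rbinom(length(H), 1, keep_prob) / keep_prob,
                         nrow(H), ncol(H))
          H <- H * mask
        }
        caches[[li]] <- list(input = flat, pre = Z, mask = mask)
        flat <- H
      } else {
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        P <- E / rowSums(E)
        caches[[li]] <- list(input = flat, prob = P)
        return(list(prob = P, caches = caches))
      }
    }
  }
}

# backward pass; y01 in {0,1}; returns per-layer gradients
.convnet_backward <- function(layers, caches, y01) {
  n <- length(y01)
  out_i <- length(layers)
  P <- caches[[out_i]]$prob
  Y <- cbind(1 - y01, y01)
  dZ <- (P - Y) / n
  grads <- vector("list", length(layers))
  dflat <- NULL
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    if (lay$type == "out") {
      grads[[li]] <- list(dW = crossprod(caches[[li]]$input, dZ),
                          db = colSums(dZ))
      dflat <- dZ %*% t(lay$W)
    } else if (lay$type == "fc") {
      if (!is.null(caches[[li]]$mask)) dflat <- dflat * caches[[li]]$mask
      dZf <- dflat * .dleaky(caches[[li]]$pre)
      grads[[li]] <- list(dW = crossprod(caches[[li]]$input, dZf),
                          db = colSums(dZf))
      dflat <- dZf %*% t(lay$W)
    } else {
      # entering the conv stack: un-flatten if coming from an fc/out layer
      pf <- caches[[li]]$pool
      dP <- array(dflat, dim(pf$P))
      dA <- .pool_backward(pf, dP)
      dpre <- dA * .dleaky(caches[[li]]$pre)
      cb <- .conv_backward(caches[[li]]$conv, lay$W, lay$w, dpre)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      d <- dim(cb$dX)
      dflat <- matrix(cb$dX, d[1], d[2] * d[3])
    }
  }
  grads
}

#' Fit the 1-D convolutional CDR classifier
#'
#' Trains a convolutional network on position-major flattened Kidera
#' feature rows (see [encode_repertoire()]): `n_conv_layers` units of
#' convolution (kernel width `kernel_width` along the 33 positions over 10
#' input channels), LeakyReLU (slope 0.2) and max-pooling (width
#' `pool_width`), then `n_fc_layers` fully connected LeakyReLU layers with
#' inverted dropout at keep-probability `dropout_rate`, and a 2-way softmax.
#' Optimized with Adam at `initial_learning_rate`, minibatch size 100.
#'
#' @param x numeric matrix, rows = sequences, 330 columns.
#' @param y01 integer 0/1 labels (1 = tumor).
#' @param hyper named list: `initial_learning_rate`, `dropout_rate`
#'   (keep-probability), `n_conv_layers`, `n_kernels`, `kernel_width`,
#'   `pool_width`, `n_fc_layers`, `fc_units`.
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 100).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param positions,channels geometry of the input rows.
#' @return a `convnet` model object.
#' @export
fit_convnet <- function(x, y01, hyper, epochs = 30, batch_size = 100,
                        seed = 1, positions = 33, channels = 10) {
  .assert(all(y01 %in% c(0, 1)), "y01 must be 0/1")
  withr::local_seed(.subseed(seed, 3))
  X3 <- .to_array(x, positions, channels)
  layers <- .convnet_init(hyper, positions, channels)
  # Adam state
  mom <- lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                         mb = 0 * l$b, vb = 0 * l$b))
  lr <- hyper$initial_learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      if (length(idx) < 2) next
      fw <- .convnet_forward(layers, X3[idx, , , drop = FALSE],
                             keep_prob = hyper$dropout_rate, train = TRUE)
      gr <- .convnet_backward(layers, fw$caches, y01[idx])
      t <- t + 1
      for (li in seq_along(layers)) {
        g <- gr[[li]]
        mom[[li]]$mW <- b1 * mom[[li]]$mW + (1 - b1) * g$dW
        mom[[li]]$vW <- b2 * mom[[li]]$vW + (1 - b2) * g$dW^2
        mom[[li]]$mb <- b1 * mom[[li]]$mb + (1 - b1) * g$db
        mom[[li]]$vb <- b2 * mom[[li]]$vb + (1 - b2) * g$db^2
        mhW <- mom[[li]]$mW / (1 - b1^t); vhW <- mom[[li]]$vW / (1 - b2^t)
        mhb <- mom[[li]]$mb / (1 - b1^t); vhb <- mom[[li]]$vb / (1 - b2^t)
        layers[[li]]$W <- layers[[li]]$W - lr * mhW / (sqrt(vhW) + eps)
        layers[[li]]$b <- layers[[li]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  structure(list(layers = layers, hyper = hyper, positions = positions,
                 channels = channels), class = "convnet")
}

#' Predict tumor probabilities from a fitted convnet
#' @param model a `convnet` from [fit_convnet()].
#' @param x feature matrix as in [fit_convnet()].
#' @return numeric vector of tumor probabilities.
#' @export
predict_convnet <- function(model, x) {
  X3 <- .to_array(x, model$positions, model$channels)
  .convnet_forward(model$layers, X3, keep_prob = 1, train = FALSE)$prob[, 2]
}
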