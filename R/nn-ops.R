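# Minimal neural-network primitives used by the feature extractor and the
# graph network: im2col convolution with cached index tables, 2x2 average
# pooling, and Adam / momentum-SGD parameter updates. Everything operates on
# plain numeric arrays; layout for image batches is H x W x C x B.
#
# Backward passes are derived by hand and verified against finite differences
# in the test suite.

.nn_cache <- new.env(parent = emptyenv())

# Index table mapping im2col columns into a zero-padded H+2p x W+2p x C image.
# Row order: output positions (h fastest, then w); column order: patch offsets
# dh fastest, then dw, then channel. Each column holds distinct indices, so
# col2im scatter-adds column-by-column without collisions.
im2col_index <- function(H, W, C, k) {
  key <- paste("idx", H, W, C, k, sep = ".")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  pad <- k %/% 2L
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  off <- seq_len(k) - 1L
  idx <- matrix(0L, H * W, k * k * C)
  j <- 0L
  for (cc in seq_len(C)) {
    for (dw in off) {
      for (dh in off) {
        j <- j + 1L
        idx[, j] <- (h + dh) + (w + dw - 1L) * Hp + (cc - 1L) * (Hp * Wp)
      }
    }
  }
  .nn_cache[[key]] <- idx
  idx
}

# Batched index table: rows ordered image-major (all positions of image 1,
# then image 2, ...).
im2col_index_batch <- function(H, W, C, k, B) {
  key <- paste("idxb", H, W, C, k, B, sep = ".")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  idx <- im2col_index(H, W, C, k)
  pad <- k %/% 2L
  per <- (H + 2L * pad) * (W + 2L * pad) * C
  out <- idx[rep(seq_len(nrow(idx)), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * per, each = nrow(idx))
  .nn_cache[[key]] <- out
  out
}

pad_batch <- function(X, pad) {
  d <- dim(X)
  if (pad == 0L) return(X)
  Xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  Xp
}

# X: H x W x Cin x B; Wmat: (k^2 Cin) x Cout; bias: length Cout or NULL.
# Returns list(out = H x W x Cout x B, cols) -- cols retained for backward.
conv2d_forward <- function(X, Wmat, bias = NULL, k) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  stop_if(nrow(Wmat) != k * k * C, "conv2d: weight/input channel mismatch")
  IDX <- im2col_index_batch(H, W, C, k, B)
  Xp <- pad_batch(X, k %/% 2L)
  cols <- Xp[as.vector(IDX)]
  dim(cols) <- dim(IDX)
  Y <- cols %*% Wmat
  if (!is.null(bias)) Y <- sweep(Y, 2L, bias, "+")
  out <- aperm(array(Y, c(H, W, B, ncol(Wmat))), c(1L, 2L, 4L, 3L))
  list(out = out, cols = cols, H = H, W = W, C = C, B = B, k = k)
}

# dOut: H x W x Cout x B. Returns grads for weights/bias and input.
conv2d_backward <- function(cache, Wmat, dOut, need_input_grad = TRUE,
                            need_weight_grad = TRUE) {
  H <- cache$H; W <- cache$W; C <- cache$C; B <- cache$B; k <- cache$k
  dYm <- matrix(aperm(dOut, c(1L, 2L, 4L, 3L)), B * H * W, dim(dOut)[3])
  dW <- if (need_weight_grad) crossprod(cache$cols, dYm) else NULL
  db <- if (need_weight_grad) colSums(dYm) else NULL
  dX <- NULL
  if (need_input_grad) {
    dcols <- tcrossprod(dYm, Wmat)
    pad <- k %/% 2L
    Hp <- H + 2L * pad
    Wp <- W + 2L * pad
    IDX <- im2col_index_batch(H, W, C, k, B)
    dXp <- numeric(Hp * Wp * C * B)
    for (j in seq_len(ncol(IDX))) {
      ij <- IDX[, j]
      dXp[ij] <- dXp[ij] + dcols[, j]
    }
    dXp <- array(dXp, c(Hp, Wp, C, B))
    dX <- dXp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# Depthwise weight matrix applying one shared k x k kernel to each of C
# channels with no cross-channel mixing.
depthwise_weight <- function(kernel, C) {
  k <- nrow(kernel)
  Wd <- matrix(0, k * k * C, C)
  kv <- as.vector(kernel)
  for (cc in seq_len(C)) {
    Wd[(cc - 1L) * k * k + seq_len(k * k), cc] <- kv
  }
  Wd
}

conv2d_depthwise <- function(X, kernel) {
  C <- dim(X)[3]
  Wd <- depthwise_weight(kernel, C)
  conv2d_forward(X, Wd, bias = NULL, k = nrow(kernel))$out
}

# 2x2 average pooling with stride 2 (even H, W).
avgpool2_forward <- function(X) {
  d <- dim(X)
  stop_if(d[1] %% 2 != 0 || d[2] %% 2 != 0, "avgpool2: H and W must be even")
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  (X[io, jo, , , drop = FALSE] + X[io + 1L, jo, , , drop = FALSE] +
     X[io, jo + 1L, , , drop = FALSE] + X[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(dY, in_dim) {
  dX <- array(0, in_dim)
  io <- seq(1L, in_dim[1], by = 2L)
  jo <- seq(1L, in_dim[2], by = 2L)
  g <- dY / 4
  dX[io, jo, , ] <- g
  dX[io + 1L, jo, , ] <- g
  dX[io, jo + 1L, , ] <- g
  dX[io + 1L, jo + 1L, , ] <- g
  dX
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)   # clones shape and attributes
  list(m = zeros, v = zeros, t = 0L)
}

adam_update <- function(params, grads, st, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

sgd_init <- function(params) {
  list(v = lapply(params, function(p) p * 0))
}

sgd_update <- function(params, grads, st, lr, momentum = 0.9) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$v[[nm]] <- momentum * st$v[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * st$v[[nm]]
  }
  list(params = params, state = st)
}

# He-style seeded initialisation for a weight matrix with fan_in rows.
he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}
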