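# Low-level tensor operations with hand-derived backward passes.
#
# Batched feature maps are stored as H x W x C x N arrays (column-major, so
# spatial indices vary fastest). Convolution is evaluated as a sum over
# kernel offsets of strided slices times per-offset weight matrices, which
# routes the bulk of the arithmetic through BLAS matrix products. No
# deep-learning framework is available in this stack, so these primitives
# are authored here and verified against brute-force nested-loop oracles in
# the test suite.

tensor_dims <- function(X) {
  d <- dim(X)
  list(H = d[1], W = d[2], C = d[3], N = d[4])
}

pad_tensor <- function(X, p, value = 0) {
  if (p == 0) return(X)
  d <- dim(X)
  Xp <- array(value, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  Xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- X
  Xp
}

conv_out_size <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# weight layout: kh x kw x Cin x Cout
nn_conv2d_forward <- function(X, W, stride = 1, pad = 0) {
  d <- dim(X); dw <- dim(W)
  if (d[3] != dw[3]) stop_mismatch("conv input channels", dw[3], d[3])
  kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  Ho <- conv_out_size(d[1], kh, stride, pad)
  Wo <- conv_out_size(d[2], kw, stride, pad)
  N <- d[4]
  Xp <- pad_tensor(X, pad)
  Yd <- matrix(0, Ho * Wo * N, Cout)
  for (ki in seq_len(kh)) {
    ri <- seq.int(ki, by = stride, length.out = Ho)
    for (kj in seq_len(kw)) {
      cj <- seq.int(kj, by = stride, length.out = Wo)
      M <- matrix(aperm(Xp[ri, cj, , , drop = FALSE], c(1, 2, 4, 3)),
                  Ho * Wo * N, Cin)
      Yd <- Yd + M %*% matrix(W[ki, kj, , ], Cin, Cout)
    }
  }
  out <- aperm(array(Yd, c(Ho, Wo, N, Cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(Xp = Xp, in_dim = d))
}

nn_conv2d_backward <- function(dY, W, cache, stride = 1, pad = 0,
                               need_dw = TRUE) {
  dw <- dim(W)
  kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  dd <- dim(dY)
  Ho <- dd[1]; Wo <- dd[2]; N <- dd[4]
  Xp <- cache$Xp
  dYd <- matrix(aperm(dY, c(1, 2, 4, 3)), Ho * Wo * N, Cout)
  dW <- if (need_dw) array(0, dim = dw) else NULL
  dXp <- array(0, dim = dim(Xp))
  for (ki in seq_len(kh)) {
    ri <- seq.int(ki, by = stride, length.out = Ho)
    for (kj in seq_len(kw)) {
      cj <- seq.int(kj, by = stride, length.out = Wo)
      Wk <- matrix(W[ki, kj, , ], Cin, Cout)
      if (need_dw) {
        M <- matrix(aperm(Xp[ri, cj, , , drop = FALSE], c(1, 2, 4, 3)),
                    Ho * Wo * N, Cin)
        dW[ki, kj, , ] <- crossprod(M, dYd)
      }
      dM <- tcrossprod(dYd, Wk)  # (Ho*Wo*N) x Cin
      dXs <- aperm(array(dM, c(Ho, Wo, N, Cin)), c(1, 2, 4, 3))
      dXp[ri, cj, , ] <- dXp[ri, cj, , , drop = FALSE] + dXs
    }
  }
  d <- cache$in_dim
  dX <- if (pad > 0) {
    dXp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW)
}

# ---- batch normalization (2-D over H, W, N per channel) ----

nn_bn2d_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

nn_bn2d_forward <- function(X, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  n <- d[1] * d[2] * d[4]
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), n, d[3])
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    v <- pmax(v, 0)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    unb <- if (n > 1) v * n / (n - 1) else v
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * unb
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu, "-"), 2, invstd, "*")
  Ym <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  out <- aperm(array(Ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, dims = d,
                    training = training))
}

nn_bn2d_backward <- function(dY, bn, cache) {
  d <- cache$dims
  n <- d[1] * d[2] * d[4]
  dYm <- matrix(aperm(dY, c(1, 2, 4, 3)), n, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    dxhat <- sweep(dYm, 2, bn$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dXm <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dXm <- sweep(dYm, 2, bn$gamma * cache$invstd, "*")
  }
  dX <- aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- 1-D batch normalization over an N x D matrix ----

nn_bn1d_init <- function(D) nn_bn2d_init(D)

nn_bn1d_forward <- function(X, bn, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- pmax(colMeans(X^2) - mu^2, 0)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    unb <- if (n > 1) v * n / (n - 1) else v
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * unb
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu, "-"), 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(out = out, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, training = training))
}

nn_bn1d_backward <- function(dY, bn, cache) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$training) {
    dxhat <- sweep(dY, 2, bn$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dX <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dX <- sweep(dY, 2, bn$gamma * cache$invstd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations, pooling, dropout, linear head ----

nn_relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
nn_relu_backward <- function(dY, cache) dY * cache

nn_maxpool_forward <- function(X, k = 3, stride = 2, pad = 1) {
  d <- dim(X)
  Ho <- conv_out_size(d[1], k, stride, pad)
  Wo <- conv_out_size(d[2], k, stride, pad)
  Xp <- pad_tensor(X, pad, value = -Inf)
  Y <- array(-Inf, dim = c(Ho, Wo, d[3], d[4]))
  argk <- array(0L, dim = c(Ho, Wo, d[3], d[4]))
  o <- 0L
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = stride, length.out = Ho)
    for (kj in seq_len(k)) {
      o <- o + 1L
      cj <- seq.int(kj, by = stride, length.out = Wo)
      cand <- Xp[ri, cj, , , drop = FALSE]
      upd <- cand > Y
      Y[upd] <- cand[upd]
      argk[upd] <- o
    }
  }
  list(out = Y, cache = list(argk = argk, in_dim = d, k = k,
                             stride = stride, pad = pad))
}

nn_maxpool_backward <- function(dY, cache) {
  d <- cache$in_dim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  dd <- dim(dY)
  dXp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  o <- 0L
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = stride, length.out = dd[1])
    for (kj in seq_len(k)) {
      o <- o + 1L
      cj <- seq.int(kj, by = stride, length.out = dd[2])
      contrib <- dY * (cache$argk == o)
      dXp[ri, cj, , ] <- dXp[ri, cj, , , drop = FALSE] + contrib
    }
  }
  if (pad > 0) {
    dXp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , , drop = FALSE]
  } else dXp
}

# 2x2 average pooling with stride 2 (even input sides)
nn_avgpool2_forward <- function(X) {
  d <- dim(X)
  Ho <- d[1] %/% 2; Wo <- d[2] %/% 2
  r1 <- seq.int(1, by = 2, length.out = Ho)
  c1 <- seq.int(1, by = 2, length.out = Wo)
  out <- (X[r1, c1, , , drop = FALSE] + X[r1 + 1, c1, , , drop = FALSE] +
          X[r1, c1 + 1, , , drop = FALSE] +
          X[r1 + 1, c1 + 1, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

nn_avgpool2_backward <- function(dY, cache) {
  d <- cache
  Ho <- dim(dY)[1]; Wo <- dim(dY)[2]
  dX <- array(0, dim = d)
  r1 <- seq.int(1, by = 2, length.out = Ho)
  c1 <- seq.int(1, by = 2, length.out = Wo)
  g <- dY / 4
  dX[r1, c1, , ] <- g
  dX[r1 + 1, c1, , ] <- g
  dX[r1, c1 + 1, , ] <- g
  dX[r1 + 1, c1 + 1, , ] <- g
  dX
}

# global average pooling -> N x C matrix
nn_gap_forward <- function(X) {
  d <- dim(X)
  m <- matrix(X, d[1] * d[2], d[3] * d[4])
  out <- t(matrix(colMeans(m), d[3], d[4]))
  list(out = out, cache = d)
}

nn_gap_backward <- function(dOut, cache) {
  d <- cache
  v <- as.vector(t(dOut)) / (d[1] * d[2])      # (c fastest, n slower)
  sweep_arr <- matrix(rep(v, each = d[1] * d[2]), d[1] * d[2], d[3] * d[4])
  array(sweep_arr, dim = d)
}

# global max pooling with argmax tracking -> N x C matrix
nn_gmp_forward <- function(X) {
  d <- dim(X)
  m <- matrix(X, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")  # per (c, n) column
  vals <- m[cbind(idx, seq_len(ncol(m)))]
  out <- t(matrix(vals, d[3], d[4]))
  list(out = out, cache = list(dims = d, idx = idx))
}

nn_gmp_backward <- function(dOut, cache) {
  d <- cache$dims
  dm <- matrix(0, d[1] * d[2], d[3] * d[4])
  dm[cbind(cache$idx, seq_len(ncol(dm)))] <- as.vector(t(dOut))
  array(dm, dim = d)
}

nn_dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}

nn_dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

nn_linear_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, "+"), cache = X)
}

nn_linear_backward <- function(dY, W, cache) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache, dY),
       db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# mean cross-entropy over the batch; returns loss and d(loss)/d(logits)
nn_softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  picked <- P[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = P, dlogits = dZ / n)
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}
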