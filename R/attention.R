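# Convolutional block attention: channel attention (what) followed by
# spatial attention (where), each a sigmoid-gated multiplicative mask.
#
# Channel attention: M_c = sigmoid(MLP(GAP(F)) + MLP(GMP(F))), with a
# shared one-hidden-layer ReLU MLP (no biases) squeezing C -> C/r -> C.
# Spatial attention: M_s = sigmoid(conv7x7([mean_c(F'); max_c(F')])) with
# padding 3, a single bias, one output plane.
#
# Public functions take a single C x H x W feature map (the natural unit of
# the method); internal *_batch variants operate on H x W x C x N tensors
# and carry the hand-derived backward pass used in training.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create CBAM weights
#'
#' @param channels number of input channels C.
#' @param reduction squeeze ratio r (C must be divisible by r). The
#'   conventional default is 16; tiny test backbones use 4.
#' @param seed integer seed for the Kaiming-uniform initialization.
#' @return an object of class `cbam_weights` with fields `mlp_w1`
#'   (C x C/r), `mlp_w2` (C/r x C), `spatial_kernel` (7 x 7 x 2 x 1) and
#'   `spatial_bias` (scalar, initialized 0).
#' @export
cbam_weights <- function(channels, reduction = 16, seed = 1) {
  if (channels %% reduction != 0) {
    stop(sprintf("channels (%d) must be divisible by reduction (%d)",
                 channels, reduction), call. = FALSE)
  }
  hid <- channels %/% reduction
  with_seed(seed, {
    structure(list(
      mlp_w1 = kaiming_uniform(c(channels, hid), fan_in = channels),
      mlp_w2 = kaiming_uniform(c(hid, channels), fan_in = hid),
      spatial_kernel = kaiming_uniform(c(7, 7, 2, 1), fan_in = 7 * 7 * 2),
      spatial_bias = 0,
      reduction = as.integer(reduction),
      channels = as.integer(channels)
    ), class = "cbam_weights")
  })
}

as_batch1 <- function(Fmap) {
  # C x H x W -> H x W x C x 1
  d <- dim(Fmap)
  if (length(d) != 3) stop("feature map must be a C x H x W array",
                           call. = FALSE)
  array(aperm(Fmap, c(2, 3, 1)), dim = c(d[2], d[3], d[1], 1))
}

check_cbam_shape <- function(X, w) {
  C <- dim(X)[3]
  if (C != w$channels) stop_mismatch("CBAM channels", w$channels, C)
}

# shared MLP applied to a C x N descriptor matrix; returns activations too
cbam_mlp <- function(Dm, w) {
  pre <- crossprod(w$mlp_w1, Dm)          # (C/r) x N
  hid <- pmax(pre, 0)
  list(out = crossprod(w$mlp_w2, hid), pre = pre, hid = hid)
}

cbam_channel_forward <- function(X, w) {
  d <- dim(X)
  HW <- d[1] * d[2]
  m <- matrix(X, HW, d[3] * d[4])
  gap <- matrix(colMeans(m), d[3], d[4])                   # C x N
  idx <- max.col(t(m), ties.method = "first")
  gmp <- matrix(m[cbind(idx, seq_len(ncol(m)))], d[3], d[4])
  a_avg <- cbam_mlp(gap, w)
  a_max <- cbam_mlp(gmp, w)
  Mc <- sigmoid(a_avg$out + a_max$out)                     # C x N
  list(Mc = Mc, gap = gap, gmp = gmp, gmp_idx = idx,
       a_avg = a_avg, a_max = a_max)
}

cbam_spatial_forward <- function(Fp, w) {
  d <- dim(Fp)
  A <- matrix(aperm(Fp, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])  # C x HWN
  avg <- colMeans(A)
  cidx <- max.col(t(A), ties.method = "first")
  mx <- A[cbind(cidx, seq_len(ncol(A)))]
  P <- array(0, dim = c(d[1], d[2], 2, d[4]))
  P[, , 1, ] <- array(avg, c(d[1], d[2], d[4]))
  P[, , 2, ] <- array(mx, c(d[1], d[2], d[4]))
  cv <- nn_conv2d_forward(P, w$spatial_kernel, stride = 1, pad = 3)
  Ms <- sigmoid(cv$out + w$spatial_bias)                   # H x W x 1 x N
  list(Ms = Ms, P = P, cidx = cidx, conv_cache = cv$cache)
}

# broadcast helpers over the H x W x C x N layout
mul_channel <- function(X, vCN) {
  d <- dim(X)
  m <- matrix(X, d[1] * d[2], d[3] * d[4])
  m <- sweep(m, 2, as.vector(vCN), "*")
  array(m, dim = d)
}

mul_spatial <- function(X, Ms) {
  d <- dim(X)
  m <- matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  m <- m * as.vector(Ms)
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

cbam_forward_batch <- function(X, w, keep_cache = FALSE) {
  check_cbam_shape(X, w)
  ch <- cbam_channel_forward(X, w)
  Fp <- mul_channel(X, ch$Mc)
  sp <- cbam_spatial_forward(Fp, w)
  out <- mul_spatial(Fp, sp$Ms)
  cache <- if (keep_cache) list(X = X, Fp = Fp, ch = ch, sp = sp) else NULL
  list(out = out, cache = cache)
}

cbam_backward_batch <- function(dOut, w, cache) {
  X <- cache$X; Fp <- cache$Fp; ch <- cache$ch; sp <- cache$sp
  d <- dim(X)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]

  # ---- spatial stage ----
  dFp <- mul_spatial(dOut, sp$Ms)
  prod_m <- matrix(aperm(dOut * Fp, c(1, 2, 4, 3)), HW * N, C)
  dMs <- array(rowSums(prod_m), dim = c(d[1], d[2], 1, N))
  dA <- dMs * sp$Ms * (1 - sp$Ms)
  cb <- nn_conv2d_backward(dA, w$spatial_kernel, sp$conv_cache,
                           stride = 1, pad = 3)
  d_spatial_bias <- sum(dA)
  dP <- cb$dX
  # mean plane spreads evenly over channels; max plane goes to argmax channel
  davg <- as.vector(dP[, , 1, ]) / C                    # length HWN
  dmx <- as.vector(dP[, , 2, ])
  dFp_m <- matrix(aperm(dFp, c(3, 1, 2, 4)), C, HW * N)
  dFp_m <- sweep(dFp_m, 2, davg, "+")
  dFp_m[cbind(sp$cidx, seq_len(ncol(dFp_m)))] <-
    dFp_m[cbind(sp$cidx, seq_len(ncol(dFp_m)))] + dmx
  dFp <- aperm(array(dFp_m, c(C, d[1], d[2], N)), c(2, 3, 1, 4))

  # ---- channel stage ----
  dX <- mul_channel(dFp, ch$Mc)
  prod_c <- matrix(dFp * X, HW, C * N)
  dMc <- matrix(colSums(prod_c), C, N)
  da <- dMc * ch$Mc * (1 - ch$Mc)
  back_mlp <- function(br, desc) {
    dh <- w$mlp_w2 %*% da                 # (C/r) x N
    dpre <- dh * (br$pre > 0)
    list(dW2 = br$hid %*% t(da), dW1 = desc %*% t(dpre),
         ddesc = w$mlp_w1 %*% dpre)
  }
  b_avg <- back_mlp(ch$a_avg, ch$gap)
  b_max <- back_mlp(ch$a_max, ch$gmp)
  dW1 <- b_avg$dW1 + b_max$dW1
  dW2 <- b_avg$dW2 + b_max$dW2
  # descriptor gradients back into the map
  dXm <- matrix(dX, HW, C * N)
  dXm <- sweep(dXm, 2, as.vector(b_avg$ddesc) / HW, "+")
  dXm[cbind(ch$gmp_idx, seq_len(ncol(dXm)))] <-
    dXm[cbind(ch$gmp_idx, seq_len(ncol(dXm)))] + as.vector(b_max$ddesc)
  dX <- array(dXm, dim = d)

  list(dX = dX,
       grads = list(mlp_w1 = dW1, mlp_w2 = dW2,
                    spatial_kernel = cb$dW, spatial_bias = d_spatial_bias))
}

#' Channel attention mask
#'
#' @param Fmap a C x H x W feature map.
#' @param w [cbam_weights()] for C channels.
#' @return length-C vector of sigmoid gates in (0, 1).
#' @export
channel_attention <- function(Fmap, w) {
  X <- as_batch1(Fmap)
  check_cbam_shape(X, w)
  as.vector(cbam_channel_forward(X, w)$Mc)
}

#' Spatial attention mask
#'
#' @param Fmap a C x H x W (channel-refined) feature map.
#' @param w [cbam_weights()].
#' @return H x W matrix of sigmoid gates in (0, 1).
#' @export
spatial_attention <- function(Fmap, w) {
  X <- as_batch1(Fmap)
  check_cbam_shape(X, w)
  sp <- cbam_spatial_forward(X, w)
  matrix(sp$Ms[, , 1, 1], dim(X)[1], dim(X)[2])
}

#' Sequential CBAM refinement
#'
#' Applies the channel mask, then the spatial mask, each by broadcast
#' multiplication. Output shape equals input shape and, because masks lie
#' in (0, 1), refinement can only attenuate: `|F''| <= |F|` element-wise.
#'
#' @param Fmap a C x H x W feature map.
#' @param w [cbam_weights()].
#' @return refined C x H x W feature map.
#' @export
cbam_refine <- function(Fmap, w) {
  X <- as_batch1(Fmap)
  out <- cbam_forward_batch(X, w)$out
  aperm(array(out, dim = dim(out)[1:3]), c(3, 1, 2))
}
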