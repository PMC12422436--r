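# brute-force CBAM oracles used across this file
channel_mask_oracle <- function(Fm, w) {
  C <- dim(Fm)[1]
  gap <- sapply(seq_len(C), function(c) mean(Fm[c, , ]))
  gmp <- sapply(seq_len(C), function(c) max(Fm[c, , ]))
  mlp <- function(d) as.vector(t(w$mlp_w2) %*% pmax(t(w$mlp_w1) %*% d, 0))
  1 / (1 + exp(-(mlp(gap) + mlp(gmp))))
}

spatial_mask_oracle <- function(Fm, w) {
  H <- dim(Fm)[2]; W <- dim(Fm)[3]
  avgp <- apply(Fm, c(2, 3), mean)
  maxp <- apply(Fm, c(2, 3), max)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- w$spatial_bias
    for (a in 1:7) for (b in 1:7) {
      ii <- i + a - 4; jj <- j + b - 4
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        s <- s + w$spatial_kernel[a, b, 1, 1] * avgp[ii, jj] +
          w$spatial_kernel[a, b, 2, 1] * maxp[ii, jj]
      }
    }
    out[i, j] <- 1 / (1 + exp(-s))
  }
  out
}

refine_oracle <- function(Fm, w) {
  mc <- channel_mask_oracle(Fm, w)
  Fp <- Fm
  for (c in seq_len(dim(Fm)[1])) Fp[c, , ] <- Fm[c, , ] * mc[c]
  ms <- spatial_mask_oracle(Fp, w)
  out <- Fp
  for (c in seq_len(dim(Fm)[1])) out[c, , ] <- Fp[c, , ] * ms
  out
}

test_that("zero attention weights give 0.5 masks and quarter refinement", {
  w <- cbam_weights(4, reduction = 4, seed = 1)
  w$mlp_w1[] <- 0; w$mlp_w2[] <- 0
  w$spatial_kernel[] <- 0; w$spatial_bias <- 0
  Fm <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(channel_attention(Fm, w), rep(0.5, 4))
  expect_equal(spatial_attention(Fm, w), matrix(0.5, 3, 3))
  expect_equal(cbam_refine(Fm, w), 0.25 * Fm)
  expect_equal(cbam_refine(array(0, c(4, 3, 3)), cbam_weights(4, 4, 2)),
               array(0, c(4, 3, 3)))
})

test_that("1x1 spatial maps collapse the two pooled descriptors", {
  w <- cbam_weights(4, reduction = 4, seed = 3)
  x <- rnorm(4)
  Fm <- array(x, c(4, 1, 1))
  mlp <- function(d) as.vector(t(w$mlp_w2) %*% pmax(t(w$mlp_w1) %*% d, 0))
  expect_equal(channel_attention(Fm, w),
               1 / (1 + exp(-2 * mlp(x))))
})

test_that("channel-constant input makes the mean and max planes agree", {
  w <- cbam_weights(3, reduction = 3, seed = 4)
  plane <- matrix(rnorm(25), 5, 5)
  Fm <- array(rep(plane, each = 3), c(3, 5, 5))
  for (c in 1:3) Fm[c, , ] <- plane
  expect_equal(spatial_attention(Fm, w), spatial_mask_oracle(Fm, w))
  # duplicated plane through both kernel slices
  wk <- w$spatial_kernel[, , 1, 1] + w$spatial_kernel[, , 2, 1]
  merged <- w
  merged$spatial_kernel[, , 1, 1] <- wk
  merged$spatial_kernel[, , 2, 1] <- 0
  expect_equal(spatial_attention(Fm, w), spatial_attention(Fm, merged))
})

test_that("attention matches brute-force oracles on random instances", {
  set.seed(12)
  for (i in 1:3) {
    C <- sample(c(4, 8), 1)
    H <- sample(3:9, 1); W <- sample(3:9, 1)
    w <- cbam_weights(C, reduction = 4, seed = 100 + i)
    Fm <- array(rnorm(C * H * W), c(C, H, W))
    expect_equal(channel_attention(Fm, w), channel_mask_oracle(Fm, w),
                 tolerance = 1e-10)
    expect_equal(spatial_attention(Fm, w), spatial_mask_oracle(Fm, w),
                 tolerance = 1e-10)
    expect_equal(cbam_refine(Fm, w), refine_oracle(Fm, w),
                 tolerance = 1e-10)
  }
})

test_that("refinement only attenuates and preserves shape", {
  set.seed(13)
  for (i in 1:3) {
    w <- cbam_weights(8, reduction = 4, seed = i)
    Fm <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
    out <- cbam_refine(Fm, w)
    expect_equal(dim(out), dim(Fm))
    expect_true(all(abs(out) <= abs(Fm) + 1e-12))
    m <- channel_attention(Fm, w)
    expect_true(all(m > 0 & m < 1))
  }
})

test_that("channel masks are equivariant under channel permutation", {
  w <- cbam_weights(6, reduction = 3, seed = 9)
  Fm <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  perm <- c(3, 1, 6, 2, 5, 4)
  wp <- w
  wp$mlp_w1 <- w$mlp_w1[perm, , drop = FALSE]
  wp$mlp_w2 <- w$mlp_w2[, perm, drop = FALSE]
  expect_equal(channel_attention(Fm[perm, , ], wp),
               channel_attention(Fm, w)[perm])
})

test_that("reduction must divide the channel count", {
  expect_error(cbam_weights(6, reduction = 4), "divisible")
  expect_error(channel_attention(array(0, c(5, 2, 2)),
                                 cbam_weights(4, 4)), "channels")
})
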