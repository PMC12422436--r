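# Shared fixtures, built once per test run. Everything is generated in code
# with fixed seeds; nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

# small preprocessed smids3 set at 32 px for fast network-level tests
tiny_set <- function() {
  if (is.null(fixture_env$tiny_set)) {
    spec <- synthetic_spec("smids3", n_per_class = 8, image_size = 32,
                           noise_sd = 0.05, deform_strength = 0.8, seed = 11)
    set <- generate_dataset(spec)
    cfg <- preprocess_config(resize_to = 32)
    set$images <- lapply(set$images, preprocess_pipeline, cfg = cfg)
    fixture_env$tiny_set <- set
  }
  fixture_env$tiny_set
}

# an untrained (but batch-norm initialized) tiny network at 32 px input
tiny_net <- function() {
  if (is.null(fixture_env$tiny_net)) {
    fixture_env$tiny_net <-
      build_network(backbone_config("tiny", input_size = 32), 3, seed = 11)
  }
  fixture_env$tiny_net
}

# gap/gmp features of the tiny set under the untrained tiny net
tiny_features <- function() {
  if (is.null(fixture_env$tiny_features)) {
    net <- tiny_net()
    set <- tiny_set()
    fixture_env$tiny_features <-
      list(gap = extract_features(net, set, "gap"),
           gmp = extract_features(net, set, "gmp"))
  }
  fixture_env$tiny_features
}

# brute-force 2-D convolution with reflect padding (oracle)
conv2d_oracle <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- reflect(i + a - 1 - ph, H)
      jj <- reflect(j + b - 1 - pw, W)
      s <- s + k[a, b] * m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# second-moment fitted-ellipse axis ratio of the thresholded bright object
moment_axis_ratio <- function(img) {
  m <- if (length(dim(img)) == 3) img[, , 1] else img
  b <- m > (min(m) + 0.5 * (max(m) - min(m)))
  idx <- which(b, arr.ind = TRUE)
  idx <- sweep(idx, 2, colMeans(idx), "-")
  S <- crossprod(idx) / nrow(idx)
  ev <- eigen(S, symmetric = TRUE)$values
  sqrt(ev[1] / max(ev[2], 1e-12))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
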