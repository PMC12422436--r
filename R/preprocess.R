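# Three-stage image preprocessing: contrast enhancement by min-max
# stretching, Gaussian denoising, and unsharp-mask sharpening, followed by
# an optional bilinear resize. Images are H x W matrices or H x W x C
# arrays; convolutions use reflect padding so borders stay bright-neutral.

#' Preprocessing configuration
#'
#' @param denoise_sigma sd (pixels) of the denoising Gaussian kernel.
#' @param denoise_ksize odd kernel side (>= 3) for denoising.
#' @param sharpen_alpha unsharp-mask coefficient (>= 0); 0 disables.
#' @param sharpen_sigma sd (pixels) of the unsharp-mask blur kernel.
#' @param resize_to output square side in pixels, or `NULL` to keep size.
#'   Default 224, at which a standard 50-layer backbone's final stage is
#'   7 x 7 x 2048.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(denoise_sigma = 1.0, denoise_ksize = 5,
                              sharpen_alpha = 1.5, sharpen_sigma = 2.0,
                              resize_to = 224) {
  stopifnot(denoise_sigma > 0, sharpen_sigma > 0, sharpen_alpha >= 0,
            denoise_ksize >= 3, denoise_ksize %% 2 == 1)
  structure(list(denoise_sigma = denoise_sigma,
                 denoise_ksize = as.integer(denoise_ksize),
                 sharpen_alpha = sharpen_alpha,
                 sharpen_sigma = sharpen_sigma,
                 resize_to = if (is.null(resize_to)) NULL
                             else as.integer(resize_to)),
            class = "preprocess_config")
}

#' Normalized 2-D Gaussian kernel
#'
#' @param ksize odd kernel side.
#' @param sigma standard deviation in pixels.
#' @return a `ksize x ksize` matrix summing to 1.
#' @export
gaussian_kernel <- function(ksize, sigma) {
  stopifnot(ksize %% 2 == 1, sigma > 0)
  r <- (ksize - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2-D convolution of a single-channel matrix with reflect padding
conv2d_reflect <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  H <- nrow(m); W <- ncol(m)
  if (kh > H || kw > W) {
    stop(sprintf("kernel size %dx%d exceeds image size %dx%d",
                 kh, kw, H, W), call. = FALSE)
  }
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  ri <- c(rev(seq_len(ph) + 1L), seq_len(H), H - seq_len(ph))
  ci <- c(rev(seq_len(pw) + 1L), seq_len(W), W - seq_len(pw))
  mp <- m[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + kernel[i, j] * mp[i:(i + H - 1), j:(j + W - 1)]
    }
  }
  out
}

apply_per_channel <- function(img, f) {
  if (length(dim(img)) == 3) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- f(img[, , c])
    out
  } else {
    f(img)
  }
}

#' Contrast enhancement by global min-max stretching
#'
#' Maps intensities linearly so the minimum becomes 0 and the maximum 1,
#' jointly over all channels. A constant image cannot be stretched and is
#' returned as all zeros with a warning.
#'
#' @param img H x W matrix or H x W x C array.
#' @return image with values in `[0, 1]`.
#' @export
enhance <- function(img) {
  stopifnot(length(img) > 0)
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    warning("constant image: intensity range is zero, returning all zeros")
    return(img * 0)
  }
  (img - lo) / (hi - lo)
}

#' Gaussian denoising
#'
#' Convolves each channel with a normalized Gaussian kernel using reflect
#' padding; constant images are fixed points since the kernel sums to 1.
#'
#' @param img normalized image.
#' @param cfg a [preprocess_config()].
#' @return denoised image, same shape.
#' @export
denoise <- function(img, cfg = preprocess_config()) {
  k <- gaussian_kernel(cfg$denoise_ksize, cfg$denoise_sigma)
  apply_per_channel(img, function(m) conv2d_reflect(m, k))
}

#' Unsharp-mask sharpening
#'
#' Adds back a scaled high-frequency component: the blurred image is
#' subtracted from the input and the difference, weighted by
#' `sharpen_alpha`, is added on top. Output is clipped to `[0, 1]`.
#'
#' @param img denoised image.
#' @param cfg a [preprocess_config()].
#' @return sharpened image, same shape.
#' @export
sharpen <- function(img, cfg = preprocess_config()) {
  if (cfg$sharpen_alpha == 0) return(img)
  ks <- 2L * as.integer(ceiling(3 * cfg$sharpen_sigma)) + 1L
  d <- if (length(dim(img)) == 3) dim(img)[1:2] else dim(img)
  ks <- min(ks, 2L * ((min(d) - 1L) %/% 2L) + 1L)
  k <- gaussian_kernel(ks, cfg$sharpen_sigma)
  blur <- apply_per_channel(img, function(m) conv2d_reflect(m, k))
  pmin(pmax(img + cfg$sharpen_alpha * (img - blur), 0), 1)
}

#' Bilinear resize to a square size
#'
#' @param img H x W matrix or H x W x C array.
#' @param size output side in pixels.
#' @return resized image.
#' @export
resize_bilinear <- function(img, size) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (H == size && W == size) return(img)
  # half-pixel-centre sampling convention
  src_y <- pmin(pmax((seq_len(size) - 0.5) * H / size - 0.5, 0), H - 1)
  src_x <- pmin(pmax((seq_len(size) - 0.5) * W / size - 0.5, 0), W - 1)
  y0 <- pmin(floor(src_y), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(floor(src_x), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- src_y - y0; wx <- src_x - x0
  interp <- function(m) {
    a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
    b <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
    cc <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
    d2 <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
    a + b + cc + d2
  }
  if (length(d) == 3) {
    out <- array(0, dim = c(size, size, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- interp(img[, , c])
    out
  } else {
    interp(img)
  }
}

#' Full preprocessing pipeline
#'
#' enhance -> denoise -> sharpen, then optional bilinear resize. Channel
#' count is preserved; output values lie in `[0, 1]`.
#'
#' @param img raw image (any numeric range, e.g. 0..255 integers).
#' @param cfg a [preprocess_config()].
#' @return preprocessed image.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  out <- sharpen(denoise(enhance(img), cfg), cfg)
  if (!is.null(cfg$resize_to)) out <- resize_bilinear(out, cfg$resize_to)
  out
}
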