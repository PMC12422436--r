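# Explainability: Grad-CAM saliency over the final refined feature map and
# 2-D embeddings of the deep feature spaces.

#' Grad-CAM heatmap
#'
#' Channel weights are the spatial means of the gradient of the target
#' class's pre-softmax score with respect to the chosen activation map;
#' the heatmap is ReLU(sum_c w_c A_c), bilinearly upsampled to the input
#' size and min-max normalized (constant maps give all zeros). The
#' gradient through the inference-mode head (GAP/GMP concatenation, 1-D
#' batch-norm, classifier row) is evaluated in closed form.
#'
#' @param net a trained `cbam_resnet`.
#' @param image one preprocessed H x W x 3 image at the network input
#'   size.
#' @param target_class 1-based class index.
#' @param layer `"cbam"` (final refined map, default) or `"backbone"`
#'   (pre-refinement final stage).
#' @return object of class `heatmap`: H x W matrix in `[0, 1]` with
#'   attributes `target_class` and `source_layer`.
#' @export
grad_cam <- function(net, image, target_class, layer = c("cbam", "backbone")) {
  layer <- match.arg(layer)
  if (!(target_class %in% seq_len(net$n_classes))) {
    stop(sprintf("target_class must be in 1..%d", net$n_classes),
         call. = FALSE)
  }
  if (layer == "backbone" && !net$use_cbam) layer <- "cbam"  # same site
  X <- images_to_tensor(list(image), net$cfg$input_size)
  # keep the CBAM cache so gradients can cross the final refinement
  fw <- forward_net(net, X, training = FALSE, keep_cache = TRUE)
  A <- fw$features$final_map                      # H x W x C x 1
  d <- dim(A)
  HW <- d[1] * d[2]; C <- d[3]

  # d(logit_t)/d(combined) through inference-mode batch-norm
  invstd <- 1 / sqrt(net$head$bn$run_var + 1e-5)
  dcomb <- net$head$W[, target_class] * net$head$bn$gamma * invstd
  dgap <- dcomb[1:C]; dgmp <- dcomb[(C + 1):(2 * C)]
  # gradient at the final refined map: GAP spreads, GMP hits the argmax
  dA_m <- matrix(rep(dgap / HW, each = HW), HW, C)
  gidx <- fw$gmp_idx                              # one argmax per channel
  dA_m[cbind(gidx, seq_len(C))] <- dA_m[cbind(gidx, seq_len(C))] + dgmp
  dA <- array(dA_m, dim = d)

  if (layer == "backbone") {
    cb <- cbam_backward_batch(dA, net$cbams[[4]], fw$cache$cbams[[4]])
    dA <- cb$dX
    A <- fw$features$backbone_map
  }
  w_c <- colMeans(matrix(dA, HW, C))              # spatial gradient means
  cam <- matrix(matrix(A, HW, C) %*% w_c, d[1], d[2])
  cam <- pmax(cam, 0)
  cam <- resize_bilinear(cam, net$cfg$input_size)
  rng <- range(cam)
  cam <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
  structure(cam, target_class = target_class, source_layer = layer,
            class = c("heatmap", "matrix"))
}

#' Overlay a heatmap on an image
#'
#' Alpha-blends a blue-to-red colormapped heatmap onto the image:
#' opacity 0 returns the image, opacity 1 the pure colormap.
#'
#' @param image H x W x 3 array (or H x W matrix) in `[0, 1]`.
#' @param heatmap H x W matrix in `[0, 1]`.
#' @param opacity blend weight in `[0, 1]` (default 0.4).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
overlay <- function(image, heatmap, opacity = 0.4) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (!all(dim(image)[1:2] == dim(heatmap))) {
    stop_mismatch("overlay size", dim(image)[1:2], dim(heatmap))
  }
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(heatmap)) / 255
  cmap <- array(cols, dim = c(dim(heatmap), 3))
  (1 - opacity) * image + opacity * cmap
}

#' Write an original / heatmap / overlay triptych as PNG
#'
#' @param image preprocessed H x W x 3 image.
#' @param hm a `heatmap`.
#' @param path output PNG path.
#' @param opacity overlay opacity.
#' @return `path`, invisibly.
#' @export
write_gradcam_panel <- function(image, hm, path, opacity = 0.4) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  ov <- overlay(image, hm, opacity)
  cmap <- overlay(image * 0, hm, 1)
  panel <- array(0, dim = c(nrow(hm), 3 * ncol(hm), 3))
  panel[, seq_len(ncol(hm)), ] <- image
  panel[, ncol(hm) + seq_len(ncol(hm)), ] <- cmap
  panel[, 2 * ncol(hm) + seq_len(ncol(hm)), ] <- ov
  png::writePNG(pmin(pmax(panel, 0), 1), path)
  invisible(path)
}

#' 2-D embedding of a feature matrix
#'
#' Seeded t-SNE of the feature rows (classical metric scaling is used as
#' a deterministic fallback when Rtsne is unavailable). Pairs with
#' [write_embedding_plot()] for a class-coloured scatter.
#'
#' @param X N x D feature matrix (N >= 5).
#' @param seed embedding seed.
#' @param perplexity t-SNE perplexity; capped at `(N - 1) / 3`.
#' @return N x 2 coordinate matrix.
#' @export
embed_2d <- function(X, seed = 1, perplexity = 30) {
  X <- unclass(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 rows to embed", call. = FALSE)
  if (requireNamespace("Rtsne", quietly = TRUE)) {
    perp <- min(perplexity, floor((n - 1) / 3))
    emb <- with_seed(derive_seed(seed, "tsne"),
                     Rtsne::Rtsne(X, dims = 2, perplexity = max(perp, 1),
                                  check_duplicates = FALSE, pca = TRUE,
                                  partial_pca = FALSE,
                                  max_iter = 500, verbose = FALSE))
    emb$Y
  } else {
    stats::cmdscale(stats::dist(X), k = 2)
  }
}

#' Scatter plot of a 2-D embedding coloured by class
#'
#' @param coords N x 2 matrix from [embed_2d()].
#' @param labels integer labels.
#' @param path output PNG path.
#' @param class_names optional legend names.
#' @return `path`, invisibly.
#' @export
write_embedding_plot <- function(coords, labels, path, class_names = NULL) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(max(labels), "Dark 3")
  plot(coords[, 1], coords[, 2], col = pal[labels], pch = 19,
       xlab = "dim 1", ylab = "dim 2", main = "feature embedding")
  if (!is.null(class_names)) {
    graphics::legend("topright", legend = class_names,
                     col = pal[seq_along(class_names)], pch = 19)
  }
  invisible(path)
}
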