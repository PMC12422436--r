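# Residual backbone with bottleneck blocks, CBAM refinement after every
# stage, and a GAP+GMP classification head.
#
# Topology: 7x7 stride-2 stem conv + BN + ReLU + 3x3 stride-2 max-pool,
# then four stages of bottleneck blocks (1x1 reduce, 3x3, 1x1 expand, each
# with batch-norm; identity or projection shortcut), a CBAM module after
# each stage output, and a head that concatenates global average and max
# pooling (length 2C), applies 1-D batch-norm, dropout and an affine
# softmax classifier.

#' Backbone configuration
#'
#' The `resnet50` variant fixes the canonical stage layout (blocks
#' 3/4/6/3, output channels 256/512/1024/2048, bottleneck expansion 4,
#' 64-channel stem); `tiny` is a strictly smaller 4-stage sibling used as
#' the desk-scale vehicle (blocks 1/1/1/1, channels 16/32/64/128,
#' expansion 2, 8-channel stem).
#'
#' @param variant `"resnet50"` or `"tiny"`.
#' @param stage_blocks,stage_channels,expansion overrides for custom
#'   variants; leave `NULL` to take the variant defaults.
#' @param input_size expected square input side (224 for resnet50,
#'   64 for tiny).
#' @param pretrained optional path to a serialized checkpoint whose
#'   weights initialize the backbone; `FALSE` (default) for seeded random
#'   initialization. No network access is ever attempted.
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(variant = c("tiny", "resnet50"),
                            stage_blocks = NULL, stage_channels = NULL,
                            expansion = NULL, input_size = NULL,
                            pretrained = FALSE) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    resnet50 = list(blocks = c(3, 4, 6, 3),
                    channels = c(256, 512, 1024, 2048),
                    expansion = 4, input_size = 224),
    tiny = list(blocks = c(1, 1, 1, 1), channels = c(16, 32, 64, 128),
                expansion = 2, input_size = 64))
  stage_blocks <- as.integer(stage_blocks %||% defaults$blocks)
  stage_channels <- as.integer(stage_channels %||% defaults$channels)
  expansion <- as.integer(expansion %||% defaults$expansion)
  input_size <- as.integer(input_size %||% defaults$input_size)
  if (length(stage_blocks) != 4 || length(stage_channels) != 4) {
    stop("stage_blocks and stage_channels must each have 4 entries",
         call. = FALSE)
  }
  if (any(stage_channels %% expansion != 0)) {
    stop("stage_channels must be divisible by the bottleneck expansion",
         call. = FALSE)
  }
  structure(list(variant = variant, stage_blocks = stage_blocks,
                 stage_channels = stage_channels, expansion = expansion,
                 input_size = input_size, pretrained = pretrained),
            class = "backbone_config")
}

#' Stage-by-stage shape arithmetic
#'
#' Computes channel counts and spatial sizes of every stage output without
#' instantiating weights: stem conv (k7 s2 p3), max-pool (k3 s2 p1), then
#' stages with stride 1, 2, 2, 2.
#'
#' @param cfg a [backbone_config()].
#' @param input_size square input side (defaults to `cfg$input_size`).
#' @return data.frame with columns stage, channels, height, width.
#' @export
network_shape <- function(cfg, input_size = cfg$input_size) {
  s <- conv_out_size(input_size, 7, 2, 3)
  s <- conv_out_size(s, 3, 2, 1)
  sizes <- integer(4)
  for (i in 1:4) {
    if (i > 1) s <- conv_out_size(s, 3, 2, 1)
    sizes[i] <- s
  }
  data.frame(stage = paste0("conv", 2:5, "_x"),
             channels = cfg$stage_channels, height = sizes, width = sizes)
}

#' Feature dimensionalities of the extraction sites
#'
#' @param cfg a [backbone_config()].
#' @param input_size square input side.
#' @return named vector with entries `backbone`, `gap`, `gmp`, `combined`,
#'   `prefinal`, `cbam`. For the resnet50 variant at 224 input these are
#'   2048 / 2048 / 2048 / 4096 / 4096 / 100352.
#' @export
feature_dims <- function(cfg, input_size = cfg$input_size) {
  sh <- network_shape(cfg, input_size)
  Cf <- sh$channels[4]; hf <- sh$height[4]
  c(backbone = Cf, gap = Cf, gmp = Cf, combined = 2 * Cf,
    prefinal = 2 * Cf, cbam = Cf * hf * hf)
}

make_bottleneck <- function(in_ch, out_ch, inner, stride) {
  blk <- list(
    conv1 = kaiming_uniform(c(1, 1, in_ch, inner), fan_in = in_ch),
    bn1 = nn_bn2d_init(inner),
    conv2 = kaiming_uniform(c(3, 3, inner, inner), fan_in = 9 * inner),
    bn2 = nn_bn2d_init(inner),
    conv3 = kaiming_uniform(c(1, 1, inner, out_ch), fan_in = inner),
    bn3 = nn_bn2d_init(out_ch),
    stride = stride, proj = NULL)
  # zero-init the last batch-norm gain so each block starts as an identity
  # mapping (standard residual-network practice: stabilizes early training
  # and keeps initial features close to the shortcut path)
  blk$bn3$gamma <- rep(0, out_ch)
  if (stride != 1 || in_ch != out_ch) {
    blk$proj <- list(conv = kaiming_uniform(c(1, 1, in_ch, out_ch),
                                            fan_in = in_ch),
                     bn = nn_bn2d_init(out_ch))
  }
  blk
}

#' Build a CBAM-augmented residual network
#'
#' @param cfg a [backbone_config()].
#' @param n_classes number of output classes (>= 2).
#' @param cbam_reduction CBAM squeeze ratio; default 16 for resnet50 and 4
#'   for tiny. Set `use_cbam = FALSE` for the plain-backbone ablation.
#' @param use_cbam include CBAM modules after each stage (default TRUE).
#' @param dropout_p head dropout probability (default 0.5).
#' @param seed seed for weight initialization.
#' @return an object of class `cbam_resnet`.
#' @export
build_network <- function(cfg, n_classes, cbam_reduction = NULL,
                          use_cbam = TRUE, dropout_p = 0.5, seed = 1) {
  stopifnot(inherits(cfg, "backbone_config"), n_classes >= 2)
  cbam_reduction <- cbam_reduction %||%
    if (cfg$variant == "resnet50") 16L else 4L
  stem_ch <- cfg$stage_channels[1] %/% cfg$expansion
  net <- with_seed(derive_seed(seed, "net-init"), {
    stages <- vector("list", 4)
    in_ch <- stem_ch
    for (s in 1:4) {
      out_ch <- cfg$stage_channels[s]
      inner <- out_ch %/% cfg$expansion
      blocks <- vector("list", cfg$stage_blocks[s])
      for (b in seq_len(cfg$stage_blocks[s])) {
        stride <- if (b == 1 && s > 1) 2L else 1L
        blocks[[b]] <- make_bottleneck(in_ch, out_ch, inner, stride)
        in_ch <- out_ch
      }
      stages[[s]] <- blocks
    }
    cbams <- if (use_cbam) {
      lapply(1:4, function(s)
        cbam_weights(cfg$stage_channels[s], cbam_reduction,
                     seed = derive_seed(seed, "cbam", s)))
    } else NULL
    Cf <- cfg$stage_channels[4]
    list(
      cfg = cfg, n_classes = as.integer(n_classes),
      class_names = NULL, use_cbam = use_cbam,
      dropout_p = dropout_p, cbam_reduction = cbam_reduction,
      stem = list(conv = kaiming_uniform(c(7, 7, 3, stem_ch),
                                         fan_in = 49 * 3),
                  bn = nn_bn2d_init(stem_ch)),
      stages = stages, cbams = cbams,
      head = list(bn = nn_bn1d_init(2 * Cf),
                  W = kaiming_uniform(c(2 * Cf, n_classes),
                                      fan_in = 2 * Cf),
                  b = rep(0, n_classes)),
      history = NULL, trained = FALSE)
  })
  if (!isFALSE(cfg$pretrained)) {
    ck <- readRDS(cfg$pretrained)
    for (f in c("stem", "stages", "cbams", "head")) {
      if (!is.null(ck[[f]])) net[[f]] <- ck[[f]]
    }
  }
  class(net) <- "cbam_resnet"
  net
}

#' @export
print.cbam_resnet <- function(x, ...) {
  sh <- network_shape(x$cfg)
  cat(sprintf("cbam_resnet (%s): %d classes, CBAM %s, final map %dx%dx%d\n",
              x$cfg$variant, x$n_classes,
              if (x$use_cbam) sprintf("on (r=%d)", x$cbam_reduction) else "off",
              sh$channels[4], sh$height[4], sh$width[4]))
  invisible(x)
}

# ---- forward ----

bottleneck_forward <- function(blk, X, training, keep_cache,
                               bn_momentum = 0.1) {
  cache <- list()
  if (is.null(blk$proj)) {
    idn <- X; cache$proj <- NULL
  } else {
    # downsampling shortcut: 2x2 average pool then 1x1 conv (the avg-pool
    # projection of the ResNet-D downsampling variant), so the shortcut
    # path aggregates rather than subsamples
    xp <- X; pool_cache <- NULL
    if (blk$stride != 1) {
      ap <- nn_avgpool2_forward(X)
      xp <- ap$out
      pool_cache <- ap$cache
    }
    cvp <- nn_conv2d_forward(xp, blk$proj$conv, stride = 1, pad = 0)
    bnp <- nn_bn2d_forward(cvp$out, blk$proj$bn, training, bn_momentum)
    blk$proj$bn <- bnp$bn
    idn <- bnp$out
    cache$proj <- list(conv = cvp$cache, bn = bnp$cache, pool = pool_cache)
  }
  cv1 <- nn_conv2d_forward(X, blk$conv1, stride = 1, pad = 0)
  bn1 <- nn_bn2d_forward(cv1$out, blk$bn1, training, bn_momentum)
  blk$bn1 <- bn1$bn
  r1 <- nn_relu_forward(bn1$out)
  cv2 <- nn_conv2d_forward(r1$out, blk$conv2, stride = blk$stride, pad = 1)
  bn2 <- nn_bn2d_forward(cv2$out, blk$bn2, training, bn_momentum)
  blk$bn2 <- bn2$bn
  r2 <- nn_relu_forward(bn2$out)
  cv3 <- nn_conv2d_forward(r2$out, blk$conv3, stride = 1, pad = 0)
  bn3 <- nn_bn2d_forward(cv3$out, blk$bn3, training, bn_momentum)
  blk$bn3 <- bn3$bn
  s <- bn3$out + idn
  r3 <- nn_relu_forward(s)
  if (keep_cache) {
    cache <- c(cache, list(cv1 = cv1$cache, bn1 = bn1$cache, r1 = r1$cache,
                           cv2 = cv2$cache, bn2 = bn2$cache, r2 = r2$cache,
                           cv3 = cv3$cache, bn3 = bn3$cache, r3 = r3$cache))
  } else cache <- NULL
  list(out = r3$out, blk = blk, cache = cache)
}

bottleneck_backward <- function(blk, dOut, cache) {
  d3 <- nn_relu_backward(dOut, cache$r3)
  # residual sum splits the gradient
  b3 <- nn_bn2d_backward(d3, blk$bn3, cache$bn3)
  c3 <- nn_conv2d_backward(b3$dX, blk$conv3, cache$cv3, stride = 1, pad = 0)
  d2 <- nn_relu_backward(c3$dX, cache$r2)
  b2 <- nn_bn2d_backward(d2, blk$bn2, cache$bn2)
  c2 <- nn_conv2d_backward(b2$dX, blk$conv2, cache$cv2,
                           stride = blk$stride, pad = 1)
  d1 <- nn_relu_backward(c2$dX, cache$r1)
  b1 <- nn_bn2d_backward(d1, blk$bn1, cache$bn1)
  c1 <- nn_conv2d_backward(b1$dX, blk$conv1, cache$cv1, stride = 1, pad = 0)
  grads <- list(conv1 = c1$dW, bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = c2$dW, bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                conv3 = c3$dW, bn3 = list(gamma = b3$dgamma, beta = b3$dbeta))
  if (is.null(blk$proj)) {
    dX <- c1$dX + d3
    grads$proj <- NULL
  } else {
    bp <- nn_bn2d_backward(d3, blk$proj$bn, cache$proj$bn)
    cp <- nn_conv2d_backward(bp$dX, blk$proj$conv, cache$proj$conv,
                             stride = 1, pad = 0)
    dproj <- if (is.null(cache$proj$pool)) cp$dX
             else nn_avgpool2_backward(cp$dX, cache$proj$pool)
    dX <- c1$dX + dproj
    grads$proj <- list(conv = cp$dW,
                       bn = list(gamma = bp$dgamma, beta = bp$dbeta))
  }
  list(dX = dX, grads = grads)
}

# Full forward pass. `training` controls dropout and head/CBAM batch-norm;
# `backbone_bn_eval` keeps backbone batch-norm layers in inference mode
# (the stage-1 freeze). Returns logits/probs, extraction-site features and,
# when `keep_cache`, everything needed for the backward pass.
forward_net <- function(net, X, training = FALSE, backbone_bn_eval = FALSE,
                        keep_cache = FALSE, bn_momentum = 0.1) {
  bb_train <- training && !backbone_bn_eval
  cache <- list(stages = vector("list", 4), cbams = vector("list", 4))

  cvs <- nn_conv2d_forward(X, net$stem$conv, stride = 2, pad = 3)
  bns <- nn_bn2d_forward(cvs$out, net$stem$bn, bb_train, bn_momentum)
  net$stem$bn <- bns$bn
  rs <- nn_relu_forward(bns$out)
  mp <- nn_maxpool_forward(rs$out, 3, 2, 1)
  cache$stem <- if (keep_cache)
    list(conv = cvs$cache, bn = bns$cache, relu = rs$cache, pool = mp$cache)
  h <- mp$out
  backbone_map <- NULL
  for (s in 1:4) {
    blocks <- net$stages[[s]]
    bc <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      bf <- bottleneck_forward(blocks[[b]], h, bb_train, keep_cache,
                               bn_momentum)
      blocks[[b]] <- bf$blk
      bc[[b]] <- bf$cache
      h <- bf$out
    }
    net$stages[[s]] <- blocks
    cache$stages[[s]] <- bc
    if (s == 4) backbone_map <- h
    if (net$use_cbam) {
      cf <- cbam_forward_batch(h, net$cbams[[s]], keep_cache = keep_cache)
      cache$cbams[[s]] <- cf$cache
      h <- cf$out
    }
  }
  final_map <- h

  gap <- nn_gap_forward(final_map)
  gmp <- nn_gmp_forward(final_map)
  combined <- cbind(gap$out, gmp$out)
  bnh <- nn_bn1d_forward(combined, net$head$bn, training, bn_momentum)
  net$head$bn <- bnh$bn
  dp <- nn_dropout_forward(bnh$out, net$dropout_p, training)
  lin <- nn_linear_forward(dp$out, net$head$W, net$head$b)
  probs <- softmax_rows(lin$out)
  cache$head <- if (keep_cache)
    list(gap = gap$cache, gmp = gmp$cache, bn = bnh$cache, drop = dp$cache,
         lin = lin$cache)

  list(net = net, logits = lin$out, probs = probs,
       features = list(backbone_map = backbone_map, final_map = final_map,
                       gap = gap$out, gmp = gmp$out, combined = combined,
                       prefinal = bnh$out),
       gmp_idx = gmp$cache$idx,
       cache = if (keep_cache) cache else NULL)
}

backward_net <- function(net, cache, dlogits) {
  lb <- nn_linear_backward(dlogits, net$head$W, cache$head$lin)
  dd <- nn_dropout_backward(lb$dX, cache$head$drop)
  bb <- nn_bn1d_backward(dd, net$head$bn, cache$head$bn)
  Cf <- ncol(bb$dX) / 2
  dgap <- bb$dX[, 1:Cf, drop = FALSE]
  dgmp <- bb$dX[, (Cf + 1):(2 * Cf), drop = FALSE]
  dh <- nn_gap_backward(dgap, cache$head$gap) +
        nn_gmp_backward(dgmp, cache$head$gmp)
  grads <- list(head = list(W = lb$dW, b = lb$db,
                            bn = list(gamma = bb$dgamma, beta = bb$dbeta)),
                stages = vector("list", 4), cbams = vector("list", 4))
  for (s in 4:1) {
    if (net$use_cbam) {
      cb <- cbam_backward_batch(dh, net$cbams[[s]], cache$cbams[[s]])
      grads$cbams[[s]] <- cb$grads
      dh <- cb$dX
    }
    blocks <- net$stages[[s]]
    gb <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      bk <- bottleneck_backward(blocks[[b]], dh, cache$stages[[s]][[b]])
      gb[[b]] <- bk$grads
      dh <- bk$dX
    }
    grads$stages[[s]] <- gb
  }
  dh <- nn_maxpool_backward(dh, cache$stem$pool)
  dh <- nn_relu_backward(dh, cache$stem$relu)
  bs <- nn_bn2d_backward(dh, net$stem$bn, cache$stem$bn)
  cs <- nn_conv2d_backward(bs$dX, net$stem$conv, cache$stem$conv,
                           stride = 2, pad = 3)
  grads$stem <- list(conv = cs$dW,
                     bn = list(gamma = bs$dgamma, beta = bs$dbeta))
  grads
}

#' Classification head on a refined feature map batch
#'
#' Concatenates global average and global max pooling of the final
#' CBAM-refined map into a 2C descriptor, applies inference-mode 1-D
#' batch-norm (dropout is inactive at inference) and the affine softmax
#' classifier. Rows of the returned matrix sum to 1.
#'
#' @param net a `cbam_resnet`.
#' @param Fmap batch tensor H x W x C x N, or a single C x H x W map.
#' @return N x n_classes matrix of class probabilities.
#' @export
forward_head <- function(net, Fmap) {
  if (length(dim(Fmap)) == 3) Fmap <- as_batch1(Fmap)
  gap <- nn_gap_forward(Fmap)$out
  gmp <- nn_gmp_forward(Fmap)$out
  combined <- cbind(gap, gmp)
  bn <- nn_bn1d_forward(combined, net$head$bn, training = FALSE)
  lin <- nn_linear_forward(bn$out, net$head$W, net$head$b)
  softmax_rows(lin$out)
}

images_to_tensor <- function(images, input_size) {
  N <- length(images)
  X <- array(0, dim = c(input_size, input_size, 3, N))
  for (i in seq_len(N)) {
    img <- images[[i]]
    if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[1] != input_size || dim(img)[2] != input_size) {
      stop(sprintf("image %d has size %dx%d; network expects %dx%d",
                   i, dim(img)[1], dim(img)[2], input_size, input_size),
           call. = FALSE)
    }
    X[, , , i] <- img[, , 1:3]
  }
  X
}

#' Predict class labels and probabilities
#'
#' Runs the network in inference mode (dropout off, batch-norm using
#' running statistics). Argmax ties break toward the lowest class index.
#'
#' @param object a trained `cbam_resnet`.
#' @param images list of preprocessed H x W x 3 images at the network's
#'   input size, or a `labeled_image_set`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return list with `labels` (1-based integers) and `probs` (N x K).
#' @export
predict.cbam_resnet <- function(object, images, batch_size = 16, ...) {
  if (inherits(images, "labeled_image_set")) images <- images$images
  n <- length(images)
  probs <- matrix(0, n, object$n_classes)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (b in idx) {
    X <- images_to_tensor(images[b], object$cfg$input_size)
    fw <- forward_net(object, X, training = FALSE)
    probs[b, ] <- fw$probs
  }
  labels <- apply(probs, 1, which.max)  # first maximum = lowest class index
  list(labels = as.integer(labels), probs = probs)
}
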