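# Two-stage training: stage 1 trains only the CBAM modules and the
# classification head with the backbone frozen (parameters and batch-norm
# statistics untouched); stage 2 fine-tunes everything with a reduced
# learning rate for the backbone. Adam optimizer, cross-entropy loss with
# an L2 penalty lambda * ||theta||^2 over all parameters.

#' Training configuration
#'
#' Defaults follow the reference recipe: 30 + 30 epochs, Adam with
#' beta = (0.9, 0.999), stage-1 head/CBAM rate 1e-3, stage-2 rates 1e-5
#' (backbone) and 1e-4 (CBAM + head), weight decay 1e-4, batch size 16,
#' head dropout 0.5, and a stratified 70/15/15 train/validation/test split.
#'
#' @param stage1_epochs,stage2_epochs epochs per phase.
#' @param lr_head_stage1 stage-1 learning rate for CBAM + head.
#' @param lr_backbone_stage2,lr_head_stage2 stage-2 learning rates.
#' @param weight_decay L2 coefficient lambda.
#' @param batch_size minibatch size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param dropout_p head dropout probability.
#' @param split train/validation/test fractions (must sum to 1).
#' @param seed seed for shuffling, dropout and splitting.
#' @return an object of class `train_config`.
#' @export
train_config <- function(stage1_epochs = 30, stage2_epochs = 30,
                         lr_head_stage1 = 1e-3, lr_backbone_stage2 = 1e-5,
                         lr_head_stage2 = 1e-4, weight_decay = 1e-4,
                         batch_size = 16, beta1 = 0.9, beta2 = 0.999,
                         dropout_p = 0.5, split = c(0.70, 0.15, 0.15),
                         seed = 42) {
  stopifnot(abs(sum(split) - 1) < 1e-8, lr_head_stage1 > 0,
            lr_backbone_stage2 > 0, lr_head_stage2 > 0, weight_decay >= 0)
  structure(list(stage1_epochs = as.integer(stage1_epochs),
                 stage2_epochs = as.integer(stage2_epochs),
                 lr_head_stage1 = lr_head_stage1,
                 lr_backbone_stage2 = lr_backbone_stage2,
                 lr_head_stage2 = lr_head_stage2,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, dropout_p = dropout_p,
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

# ---- nested parameter bookkeeping ----

nested_get <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

nested_set <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- nested_set(x[[path[[1]]]], path[-1], value)
  x
}

# enumerate all trainable parameter paths with their group tag
param_paths <- function(net) {
  out <- list()
  add <- function(path, group) {
    out[[length(out) + 1L]] <<- list(path = path, group = group)
  }
  add(list("stem", "conv"), "backbone")
  add(list("stem", "bn", "gamma"), "backbone")
  add(list("stem", "bn", "beta"), "backbone")
  for (s in 1:4) {
    for (b in seq_along(net$stages[[s]])) {
      base <- list("stages", s, b)
      for (cv in c("conv1", "conv2", "conv3")) {
        add(c(base, cv), "backbone")
      }
      for (bnm in c("bn1", "bn2", "bn3")) {
        add(c(base, bnm, "gamma"), "backbone")
        add(c(base, bnm, "beta"), "backbone")
      }
      if (!is.null(net$stages[[s]][[b]]$proj)) {
        add(c(base, "proj", "conv"), "backbone")
        add(c(base, "proj", "bn", "gamma"), "backbone")
        add(c(base, "proj", "bn", "beta"), "backbone")
      }
    }
  }
  if (net$use_cbam) {
    for (s in 1:4) {
      for (f in c("mlp_w1", "mlp_w2", "spatial_kernel", "spatial_bias")) {
        add(list("cbams", s, f), "cbam")
      }
    }
  }
  add(list("head", "W"), "head")
  add(list("head", "b"), "head")
  add(list("head", "bn", "gamma"), "head")
  add(list("head", "bn", "beta"), "head")
  out
}

param_l2 <- function(net, paths) {
  sum(vapply(paths, function(p) sum(nested_get(net, p$path)^2), numeric(1)))
}

adam_init <- function(paths) {
  st <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    st[[i]] <- list(m = 0, v = 0)
  }
  st
}

adam_step <- function(net, grads, paths, state, t, lrs, cfg) {
  eps <- 1e-8
  lambda <- cfg$weight_decay
  for (i in seq_along(paths)) {
    grp <- paths[[i]]$group
    lr <- lrs[[grp]]
    if (is.null(lr)) next  # frozen group
    theta <- nested_get(net, paths[[i]]$path)
    g <- nested_get(grads, paths[[i]]$path) + 2 * lambda * theta
    st <- state[[i]]
    st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
    st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
    mhat <- st$m / (1 - cfg$beta1^t)
    vhat <- st$v / (1 - cfg$beta2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    net <- nested_set(net, paths[[i]]$path, theta)
    state[[i]] <- st
  }
  list(net = net, state = state)
}

#' Stratified train/validation/test split
#'
#' @param set a `labeled_image_set`.
#' @param split fractions summing to 1 (default 0.70/0.15/0.15).
#' @param seed shuffle seed.
#' @return list of three `labeled_image_set`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(set, split = c(0.70, 0.15, 0.15), seed = 42) {
  stopifnot(inherits(set, "labeled_image_set"), abs(sum(split) - 1) < 1e-8)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(derive_seed(seed, "split"), {
    for (c in sort(unique(set$labels))) {
      ci <- sample(which(set$labels == c))
      n <- length(ci)
      n1 <- round(split[1] * n); n2 <- round(split[2] * n)
      idx$train <- c(idx$train, ci[seq_len(n1)])
      idx$val <- c(idx$val, ci[n1 + seq_len(min(n2, n - n1))])
      idx$test <- c(idx$test, ci[setdiff(seq_len(n), seq_len(n1 + n2))])
    }
  })
  subset_set <- function(i) {
    structure(list(images = set$images[i], labels = set$labels[i],
                   class_names = set$class_names),
              class = "labeled_image_set")
  }
  lapply(idx, subset_set)
}

run_epoch <- function(net, X_all, y, cfg, paths, state, t0, lrs,
                      backbone_bn_eval) {
  n <- length(y)
  ord <- sample(n)
  batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  total_loss <- 0; total_correct <- 0
  t <- t0
  for (b in batches) {
    X <- X_all[, , , b, drop = FALSE]
    fw <- forward_net(net, X, training = TRUE,
                      backbone_bn_eval = backbone_bn_eval, keep_cache = TRUE)
    net <- fw$net
    sce <- nn_softmax_ce(fw$logits, y[b])
    loss <- sce$loss + cfg$weight_decay * param_l2(net, paths)
    grads <- backward_net(net, fw$cache, sce$dlogits)
    t <- t + 1
    upd <- adam_step(net, grads, paths, state, t, lrs, cfg)
    net <- upd$net; state <- upd$state
    total_loss <- total_loss + loss * length(b)
    total_correct <- total_correct +
      sum(apply(sce$probs, 1, which.max) == y[b])
  }
  list(net = net, state = state, t = t,
       loss = total_loss / n, acc = total_correct / n)
}

eval_accuracy <- function(net, X_all, y, batch_size) {
  n <- length(y)
  correct <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- forward_net(net, X_all[, , , b, drop = FALSE], training = FALSE)
    correct <- correct + sum(apply(fw$probs, 1, which.max) == y[b])
  }
  correct / n
}

#' Two-stage training of a CBAM residual network
#'
#' Stage 1 optimizes only CBAM and head parameters (backbone weights and
#' batch-norm statistics are bit-identical before and after); stage 2
#' unfreezes everything with per-group learning rates. The Adam state is
#' re-initialized at the start of each stage. All randomness (shuffling,
#' dropout) derives from `cfg$seed`.
#'
#' @param net a `cbam_resnet` from [build_network()].
#' @param train_set `labeled_image_set` of preprocessed images at the
#'   network input size.
#' @param val_set optional validation `labeled_image_set`.
#' @param cfg a [train_config()].
#' @return the trained network with a `history` data.frame
#'   (stage, epoch, loss, train_acc, val_acc).
#' @export
train_two_stage <- function(net, train_set, val_set = NULL,
                            cfg = train_config()) {
  stopifnot(inherits(net, "cbam_resnet"), inherits(cfg, "train_config"))
  if (length(train_set$images) == 0) stop("empty training set", call. = FALSE)
  if (length(train_set$class_names) != net$n_classes) {
    stop_mismatch("class count", net$n_classes, length(train_set$class_names))
  }
  net$dropout_p <- cfg$dropout_p
  X_all <- images_to_tensor(train_set$images, net$cfg$input_size)
  y <- train_set$labels
  X_val <- if (!is.null(val_set))
    images_to_tensor(val_set$images, net$cfg$input_size)
  paths <- param_paths(net)
  history <- NULL

  net <- with_seed(derive_seed(cfg$seed, "train"), {
    # Calibrate batch-norm running statistics on the training data before
    # stage 1: two train-mode passes with no weight updates and a high
    # statistics momentum. Without this, the frozen backbone's
    # inference-mode batch-norm would run on its initialization statistics,
    # and the switch to batch statistics in stage 2 would shift the feature
    # distribution under the trained head. Only batch-norm buffers change;
    # all weights stay bit-identical.
    for (pass in 1:2) {
      for (b in split(seq_along(y), ceiling(seq_along(y) / cfg$batch_size))) {
        fw <- forward_net(net, X_all[, , , b, drop = FALSE], training = TRUE,
                          backbone_bn_eval = FALSE, keep_cache = FALSE,
                          bn_momentum = 0.5)
        net <- fw$net
      }
    }
    for (stage in 1:2) {
      n_epochs <- if (stage == 1) cfg$stage1_epochs else cfg$stage2_epochs
      if (n_epochs == 0) next
      lrs <- if (stage == 1) {
        list(backbone = NULL, cbam = cfg$lr_head_stage1,
             head = cfg$lr_head_stage1)
      } else {
        list(backbone = cfg$lr_backbone_stage2, cbam = cfg$lr_head_stage2,
             head = cfg$lr_head_stage2)
      }
      state <- adam_init(paths)
      t <- 0
      for (ep in seq_len(n_epochs)) {
        r <- run_epoch(net, X_all, y, cfg, paths, state, t, lrs,
                       backbone_bn_eval = (stage == 1))
        net <- r$net; state <- r$state; t <- r$t
        val_acc <- if (!is.null(val_set))
          eval_accuracy(net, X_val, val_set$labels, cfg$batch_size) else NA
        history <- rbind(history,
                         data.frame(stage = stage, epoch = ep,
                                    loss = r$loss, train_acc = r$acc,
                                    val_acc = val_acc))
      }
    }
    net
  })
  net$history <- history
  net$class_names <- train_set$class_names
  net$trained <- TRUE
  net
}

#' Save / load a trained network
#'
#' The checkpoint is a serialized weight archive with a JSON sidecar
#' carrying the configuration, class names and training history.
#'
#' @param net a `cbam_resnet`.
#' @param path checkpoint file path (`.rds`; sidecar gets `.json`).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  side <- list(variant = net$cfg$variant, input_size = net$cfg$input_size,
               n_classes = net$n_classes, class_names = net$class_names,
               use_cbam = net$use_cbam, trained = net$trained,
               history = net$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "cbam_resnet"))
  net
}
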