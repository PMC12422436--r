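test_that("stride arithmetic reproduces the printed dimensionalities", {
  r50 <- backbone_config("resnet50")
  sh <- network_shape(r50, 224)
  expect_equal(sh$channels, c(256, 512, 1024, 2048))
  expect_equal(sh$height, c(56, 28, 14, 7))
  dims <- feature_dims(r50, 224)
  expect_equal(unname(dims["gap"]), 2048)
  expect_equal(unname(dims["gmp"]), 2048)
  expect_equal(unname(dims["combined"]), 4096)
  expect_equal(unname(dims["cbam"]), 100352)  # 2048 * 7 * 7

  tiny <- backbone_config("tiny", input_size = 64)
  sht <- network_shape(tiny, 64)
  expect_equal(sht$channels, c(16, 32, 64, 128))
  expect_equal(sht$height[4], 2)
})

test_that("the CBAM-free configuration is a plain backbone", {
  net <- build_network(backbone_config("tiny", input_size = 32), 3,
                       use_cbam = FALSE, seed = 1)
  expect_null(net$cbams)
  set <- tiny_set()
  pr <- predict(net, set$images[1:4])
  expect_length(pr$labels, 4)
})

test_that("the head produces a 2C descriptor and proper probabilities", {
  net <- tiny_net()
  Fm <- array(abs(rnorm(2 * 2 * 128 * 3)), c(2, 2, 128, 3))
  probs <- forward_head(net, Fm)
  expect_equal(dim(probs), c(3, 3))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_identical(probs, forward_head(net, Fm))  # inference determinism
  # descriptor length 2C: a 2048-channel map would give 4096 (checked via
  # the weight shape consistency here at C = 128)
  expect_equal(nrow(net$head$W), 2 * 128)
})

test_that("prediction breaks argmax ties toward the lowest class index", {
  net <- tiny_net()
  net$head$W[] <- 0
  net$head$b[] <- 0
  set <- tiny_set()
  pr <- predict(net, set$images[1:3])
  expect_equal(pr$labels, c(1L, 1L, 1L))
  expect_equal(pr$probs, matrix(1 / 3, 3, 3), tolerance = 1e-12)
})

test_that("batch prediction equals per-image prediction", {
  net <- tiny_net()
  set <- tiny_set()
  batch <- predict(net, set$images[1:5], batch_size = 5)
  single <- sapply(1:5, function(i)
    predict(net, set$images[i])$labels)
  expect_equal(batch$labels, as.integer(single))
})

test_that("wrong input size errors with the expected size", {
  net <- tiny_net()
  expect_error(predict(net, list(array(0, c(16, 16, 3)))), "expects 32x32")
})

test_that("analytic gradients agree with finite differences", {
  P <- asNamespace("spermdfe")
  net <- build_network(backbone_config("tiny", input_size = 32), 3,
                       dropout_p = 0, seed = 3)
  set.seed(21)
  X <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  y <- c(1L, 3L, 2L, 1L)
  loss_of <- function(n) {
    fw <- P$forward_net(n, X, training = TRUE, keep_cache = TRUE)
    P$nn_softmax_ce(fw$logits, y)$loss
  }
  fw <- P$forward_net(net, X, training = TRUE, keep_cache = TRUE)
  sce <- P$nn_softmax_ce(fw$logits, y)
  grads <- P$backward_net(net, fw$cache, sce$dlogits)
  probes <- list(list(path = list("stem", "conv"), idx = 5),
                 list(path = list("stages", 2, 1, "conv2"), idx = 7),
                 list(path = list("cbams", 1, "mlp_w2"), idx = 2),
                 list(path = list("head", "W"), idx = 11))
  eps <- 1e-5
  for (p in probes) {
    th <- P$nested_get(net, p$path)
    g <- P$nested_get(grads, p$path)[p$idx]
    th2 <- th; th2[p$idx] <- th2[p$idx] + eps
    num <- (loss_of(P$nested_set(net, p$path, th2)) - sce$loss) / eps
    expect_lt(abs(num - g), 1e-3 * max(1, abs(g)))
  }
})

test_that("the reported training loss matches an independent evaluation", {
  P <- asNamespace("spermdfe")
  set <- tiny_set()
  cfg <- train_config(stage1_epochs = 1, stage2_epochs = 0,
                      batch_size = 64, dropout_p = 0, seed = 5)
  net0 <- build_network(backbone_config("tiny", input_size = 32), 3,
                        seed = 5)
  trained <- train_two_stage(net0, set, cfg = cfg)

  # independent route: replicate the statistics-calibration pass, then
  # evaluate mean cross-entropy + lambda * ||theta||^2 on the single batch
  net <- net0
  net$dropout_p <- 0
  X <- P$images_to_tensor(set$images, 32)
  for (pass in 1:2) {
    fw <- P$forward_net(net, X, training = TRUE, bn_momentum = 0.5)
    net <- fw$net
  }
  fw <- P$forward_net(net, X, training = TRUE, backbone_bn_eval = TRUE)
  picked <- fw$probs[cbind(seq_along(set$labels), set$labels)]
  l2 <- sum(unlist(lapply(P$param_paths(net), function(p)
    sum(P$nested_get(net, p$path)^2))))
  expected <- -mean(log(picked)) + cfg$weight_decay * l2
  expect_equal(trained$history$loss[1], expected, tolerance = 1e-6)
})

test_that("two-stage training descends and freezes the backbone in stage 1", {
  spec <- synthetic_spec("smids3", n_per_class = 40, image_size = 32,
                         noise_sd = 0.05, deform_strength = 0.8, seed = 42)
  big <- generate_dataset(spec)
  pcfg <- preprocess_config(resize_to = 32)
  big$images <- lapply(big$images, preprocess_pipeline, cfg = pcfg)
  parts <- split_dataset(big, c(0.7, 0.15, 0.15), seed = 42)
  cfg <- train_config(stage1_epochs = 3, stage2_epochs = 3, seed = 42)
  net0 <- build_network(backbone_config("tiny", input_size = 32), 3,
                        seed = 42)
  net <- train_two_stage(net0, parts$train, parts$val, cfg)
  expect_true(net$trained)
  expect_equal(nrow(net$history), 6)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])

  set <- tiny_set()
  # freeze contract: after a stage-1-only run the backbone weights are
  # bit-identical to their initialization
  cfg1 <- train_config(stage1_epochs = 2, stage2_epochs = 0, seed = 42)
  net1 <- train_two_stage(net0, parts$train, cfg = cfg1)
  strip_bn_stats <- function(x) {
    if (is.list(x)) {
      x$run_mean <- NULL; x$run_var <- NULL
      lapply(x, strip_bn_stats)
    } else x
  }
  expect_identical(strip_bn_stats(net1$stem), strip_bn_stats(net0$stem))
  expect_identical(strip_bn_stats(net1$stages), strip_bn_stats(net0$stages))
  # while CBAM and head did move
  expect_false(identical(net1$head$W, net0$head$W))
  expect_false(identical(net1$cbams, net0$cbams))
})

test_that("weight decay does not inflate the parameter norm", {
  P <- asNamespace("spermdfe")
  set <- tiny_set()
  norm_of <- function(wd) {
    cfg <- train_config(stage1_epochs = 1, stage2_epochs = 2,
                        weight_decay = wd, seed = 7)
    net <- build_network(backbone_config("tiny", input_size = 32), 3,
                         seed = 7)
    net <- train_two_stage(net, set, cfg = cfg)
    sqrt(sum(unlist(lapply(P$param_paths(net), function(p)
      sum(P$nested_get(net, p$path)^2)))))
  }
  expect_lte(norm_of(1e-4), norm_of(0) + 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  set <- tiny_set()
  cfg <- train_config(stage1_epochs = 1, stage2_epochs = 1, seed = 99)
  run <- function() {
    net <- build_network(backbone_config("tiny", input_size = 32), 3,
                         seed = 99)
    net <- train_two_stage(net, set, cfg = cfg)
    predict(net, set$images[1:6])
  }
  expect_identical(run(), run())
})

test_that("checkpoints round-trip with their JSON sidecar", {
  net <- tiny_net()
  net$class_names <- c("a", "b", "c")
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_network(path)
  expect_identical(back$head, net$head)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$variant, "tiny")
})
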