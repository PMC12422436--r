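test_that("rendering is a pure function of its seed", {
  a <- render_cell(1, "smids3", 64, 0.5, seed = 7)
  b <- render_cell(1, "smids3", 64, 0.5, seed = 7)
  expect_identical(a, b)
  c <- render_cell(1, "smids3", 64, 0.5, seed = 8)
  expect_false(identical(a, c))
  expect_equal(dim(a), c(64, 64, 3))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("unknown class ids are rejected with the class list", {
  expect_error(render_cell(5, "smids3", 64, 0.5, seed = 1), "valid classes")
  expect_error(render_cell(0, "hushem4", 64, 0.5, seed = 1), "amorphous")
})

test_that("tapered heads are elongated and debris blobs are compact", {
  ratios_tapered <- sapply(1:5, function(s)
    moment_axis_ratio(render_cell(4, "hushem4", 128, 0.5, seed = s)))
  expect_true(all(ratios_tapered >= 2.0))
  # non-sperm: tail-less blob, so the fitted ellipse stays near-isotropic
  ratios_blob <- sapply(1:5, function(s)
    moment_axis_ratio(render_cell(2, "smids3", 128, 0.5, seed = s)))
  expect_true(all(ratios_blob < 2.0))
  # normal sperm carry a tail, giving a larger extent along the axis than
  # the blob class
  expect_gt(mean(sapply(1:5, function(s)
    moment_axis_ratio(render_cell(3, "smids3", 128, 0.5, seed = s)))),
    mean(ratios_blob))
})

test_that("generated datasets are balanced, shuffled and deterministic", {
  spec <- synthetic_spec("smids3", n_per_class = 10, image_size = 32, seed = 1)
  set <- generate_dataset(spec)
  expect_length(set$images, 30)
  expect_equal(unname(table(set$labels)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(set$class_names, c("abnormal_sperm", "non_sperm",
                                  "normal_sperm"))
  expect_false(all(set$labels == sort(set$labels)))  # shuffled
  expect_identical(set, generate_dataset(spec))

  h4 <- generate_dataset(synthetic_spec("hushem4", 5, 32, seed = 1))
  expect_length(h4$images, 20)
  expect_length(h4$class_names, 4)

  spec2 <- synthetic_spec("smids3", n_per_class = 10, image_size = 32,
                          seed = 2)
  set2 <- generate_dataset(spec2)
  expect_equal(unname(table(set2$labels)), rep(10L, 3), ignore_attr = TRUE)
  expect_false(identical(set$images[[1]], set2$images[[1]]))
})

test_that("image folders round-trip through the dataset reader", {
  set <- generate_dataset(synthetic_spec("smids3", 4, 32, seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_image_folder(set, dir)
  expect_equal(nrow(manifest), 12)
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                  set$class_names)
  expect_length(list.files(dir, pattern = "\\.png$", recursive = TRUE), 12)

  back <- read_image_folder(dir)
  expect_equal(back$class_names, set$class_names)
  expect_length(back$images, 12)
  expect_equal(unname(table(back$labels)), rep(4L, 3), ignore_attr = TRUE)
})

test_that("writing an empty set makes an empty manifest and no directories", {
  empty <- structure(list(images = list(), labels = integer(0),
                          class_names = c("a", "b")),
                     class = "labeled_image_set")
  dir <- withr::local_tempdir()
  manifest <- write_image_folder(empty, dir)
  expect_equal(nrow(manifest), 0)
  expect_length(list.dirs(dir, recursive = FALSE), 0)
})

test_that("a pixel-intensity kNN baseline beats chance on separable renders", {
  spec <- synthetic_spec("smids3", n_per_class = 12, image_size = 64,
                         noise_sd = 0.05, deform_strength = 0.5, seed = 5)
  set <- generate_dataset(spec)
  X <- t(sapply(set$images, function(im)
    as.vector(resize_bilinear(im[, , 1], 16))))
  y <- set$labels
  folds <- stratified_kfold(y, 3, seed = 1)
  acc <- mean(unlist(lapply(folds, function(te) {
    tr <- setdiff(seq_along(y), te)
    model <- fit_classifier(scale(X[tr, ]), y[tr], classifier_spec("knn"))
    ctr <- colMeans(X[tr, ]); s <- apply(X[tr, ], 2, sd); s[s == 0] <- 1
    Z <- sweep(sweep(X[te, ], 2, ctr, "-"), 2, s, "/")
    predict(model, Z) == y[te]
  })))
  expect_gt(acc, 1 / 3)
})
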