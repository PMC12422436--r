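# brute-force chi-square scores: min-max scale, explicit per-class sums
chi2_oracle <- function(X, y) {
  Xs <- apply(X, 2, function(col) {
    r <- range(col)
    if (r[2] == r[1]) col * 0 else (col - r[1]) / (r[2] - r[1])
  })
  sapply(seq_len(ncol(X)), function(j) {
    tot <- sum(Xs[, j])
    s <- 0
    for (c in sort(unique(y))) {
      O <- sum(Xs[y == c, j])
      E <- mean(y == c) * tot
      if (E > 0) s <- s + (O - E)^2 / E
    }
    s
  })
}

test_that("variance selection drops constant columns", {
  X <- cbind(rep(1, 10), rnorm(10))
  sel <- select_features(X, method = "variance", k = 1)
  expect_equal(sel$payload$indices, 2L)
})

test_that("chi-square scores match hand-computed contingency sums", {
  X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  y <- c(1, 1, 2, 2)
  sel <- select_features(X, y, "chi2", k = 1)
  # both features score (2-1)^2/1 + (0-1)^2/1 = 2; tie-break takes index 1
  expect_equal(sel$payload$scores, c(2, 2))
  expect_equal(sel$payload$indices, 1L)

  set.seed(31)
  for (i in 1:5) {
    N <- sample(8:20, 1); D <- sample(2:6, 1)
    X <- matrix(runif(N * D), N, D)
    y <- sample(1:3, N, replace = TRUE)
    if (length(unique(y)) < 2) next
    sel <- select_features(X, y, "chi2", k = D)
    expect_equal(sel$payload$scores, chi2_oracle(X, y), tolerance = 1e-10)
  }
})

test_that("PCA loadings align with the dominant axes", {
  set.seed(5)
  X <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1), rnorm(200, sd = 0.3))
  sel <- select_features(X, method = "pca", k = 2)
  V <- sel$payload$rotation
  expect_gt(abs(V[1, 1]), 0.99)
  expect_gt(abs(V[2, 2]), 0.99)
  # orthonormal columns
  expect_equal(unname(crossprod(V)), diag(2), tolerance = 1e-6)
  # eigen-decomposition oracle
  ev <- eigen(cov(X), symmetric = TRUE)$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(sum(V[, j] * ev[, j])), 1, tolerance = 1e-6)
  }
})

test_that("k beyond the feature count is clipped with a warning", {
  X <- matrix(rnorm(40), 10, 4)
  expect_warning(sel <- select_features(X, method = "variance", k = 9),
                 "clipped")
  expect_equal(sel$k, 4L)
})

test_that("per-feature PCA importance ranks dominant columns first", {
  set.seed(6)
  X <- cbind(rnorm(100, sd = 10), matrix(rnorm(300, sd = 0.1), 100, 3))
  imp <- pca_feature_importance(X, k = 2)
  expect_equal(which.max(imp), 1L)
  expect_true(all(imp >= 0))

  # duplicated columns get equal importance
  z <- rnorm(50)
  X2 <- cbind(z, z, rnorm(50, sd = 0.5))
  imp2 <- pca_feature_importance(X2, k = 2)
  expect_equal(imp2[1], imp2[2], tolerance = 1e-9)

  # brute-force recomputation from explicit eigenvectors
  X3 <- matrix(rnorm(20), 5, 4)
  k <- 3
  pc <- prcomp(X3, center = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  ref <- abs(pc$rotation[, 1:k]) %*% evr[1:k]
  expect_equal(pca_feature_importance(X3, k), as.numeric(ref),
               tolerance = 1e-9)
})

test_that("ten selection methods exist and intersections behave", {
  expect_length(selection_methods(), 10)
  expect_length(grep("∩", selection_methods()), 6)

  # identical rankings: duplicate scoring structure makes top-k sets equal,
  # so the intersection is the whole top-k
  set.seed(7)
  X <- matrix(rnorm(200), 20, 10)
  X[, 3] <- X[, 3] * 6; X[, 8] <- X[, 8] * 5  # variance order is clear
  y <- rep(1:2, each = 10)
  sel <- intersect_selections("pca", "variance", X, y, k = 2)
  base_var <- select_features(X, y, "variance", k = 2)
  if (setequal(sel$payload$indices, base_var$payload$indices)) {
    expect_length(sel$payload$indices, 2)
  }
  expect_true(all(sel$payload$indices %in% 1:10))

  expect_error(intersect_selections("pca", "pca", X, y, 2), "differ")
})

test_that("disjoint top-k sets fall back to the best mean-rank pair", {
  # construct rankings by hand: method A = variance, method B = chi2
  # feature 1: huge variance, no class signal; feature 2: moderate variance
  # and strong class signal; features 3,4: noise
  y <- rep(1:2, each = 10)
  set.seed(8)
  X <- cbind(rnorm(20, sd = 10),
             c(rnorm(10, 0, 0.3), rnorm(10, 3, 0.3)),
             rnorm(20, sd = 0.2), rnorm(20, sd = 0.1))
  selA <- select_features(X, y, "variance", k = 1)
  selB <- select_features(X, y, "chi2", k = 1)
  expect_false(setequal(selA$payload$indices, selB$payload$indices))
  sel <- intersect_selections("variance", "chi2", X, y, k = 1)
  # empty intersection backfills to exactly 2, the union's best mean ranks
  expect_length(sel$payload$indices, 2)
  expect_setequal(sel$payload$indices,
                  c(selA$payload$indices, selB$payload$indices))
})

test_that("applying selections respects payload type and dimensions", {
  set.seed(9)
  X <- matrix(rnorm(60), 10, 6)
  y <- rep(1:2, 5)
  all_idx <- select_features(X, y, "variance", k = 6)
  expect_equal(apply_selection(X, all_idx), X)

  # projections use the training-fold centre on held-out rows
  tr <- 1:6; te <- 7:10
  sel <- select_features(X[tr, ], method = "pca", k = 2)
  held <- apply_selection(X[te, ], sel)
  manual <- sweep(X[te, ], 2, colMeans(X[tr, ]), "-") %*%
    sel$payload$rotation
  expect_equal(held, manual, tolerance = 1e-12)

  # applying an index selection twice fails on the reduced matrix
  sub <- select_features(X, y, "variance", k = 2)
  once <- apply_selection(X, sub)
  expect_error(apply_selection(once, sub), "dimension mismatch")
})

test_that("the 8:1 reduction holds for all ten methods", {
  set.seed(10)
  for (D in c(64, 100)) {
    X <- matrix(rnorm(40 * D), 40, D)
    y <- rep(1:2, 20)
    k <- default_k(D)
    expect_equal(k, as.integer(ceiling(D / 8)))
    for (m in selection_methods()) {
      sel <- spermdfe:::fit_selector(m, X, y, k, seed = 1)
      out <- apply_selection(X, sel)
      if (m %in% c("pca", "chi2", "rf", "variance")) {
        expect_equal(ncol(out), k)
      } else {
        expect_lte(ncol(out), k)
        expect_gte(ncol(out), 2)
      }
    }
  }
})

test_that("PCA reconstruction error is non-increasing in k", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30, 8)
  err <- sapply(1:6, function(k) {
    sel <- select_features(X, method = "pca", k = k)
    Z <- apply_selection(X, sel)
    rec <- Z %*% t(sel$payload$rotation)
    sum((sweep(X, 2, sel$payload$center, "-") - rec)^2)
  })
  expect_true(all(diff(err) <= 1e-9))
})

test_that("forest importances are reproducible and fold-sensitive", {
  set.seed(12)
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[, 4] <- X[, 4] + rep(c(0, 2), each = 20)
  y <- rep(1:2, each = 20)
  s1 <- select_features(X, y, "rf", k = 3, seed = 5)
  s2 <- select_features(X, y, "rf", k = 3, seed = 5)
  expect_identical(s1$payload$scores, s2$payload$scores)

  # no leakage: a selector fitted on different training rows can differ
  s3 <- select_features(X[1:30, ], y[1:30], "rf", k = 3, seed = 5)
  expect_false(identical(s1$payload$scores, s3$payload$scores))
})
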