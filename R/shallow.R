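# Shallow classifiers over selected deep features: SVM with RBF or linear
# kernel (libsvm via e1071, one-vs-one multi-class) and a k-nearest
# neighbour classifier written here because its tie rules are part of the
# contract: distance ties break toward the lower training-row index and
# vote ties toward the lowest class index.

#' Shallow classifier specification
#'
#' @param kind `"svm_rbf"`, `"svm_linear"`, `"knn"` or `"rf"` (random
#'   forest, available for the extended grid preset).
#' @param C SVM regularization constant (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses
#'   `1 / (D * mean(var(X_train)))`.
#' @param k_neighbors kNN neighbourhood size, odd (default 3).
#' @param seed seed (used by the random forest).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "svm_linear", "knn", "rf"),
                            C = 1, gamma = NULL, k_neighbors = 3, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(C > 0, k_neighbors >= 1, k_neighbors %% 2 == 1)
  structure(list(kind = kind, C = C, gamma = gamma,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a shallow classifier
#'
#' Expects features already standardized on the training fold (mean 0,
#' sd 1; constant columns left at 0). The RBF kernel is
#' `K(x, z) = exp(-gamma * ||x - z||^2)` with
#' `gamma = 1 / (D * mean column variance)` unless given; multi-class SVM
#' uses one-vs-one voting. kNN stores the training set.
#'
#' @param X_train N x D standardized matrix.
#' @param y_train integer labels (>= 2 classes present).
#' @param spec a [classifier_spec()].
#' @return a fitted model of class `shallow_model`.
#' @export
fit_classifier <- function(X_train, y_train, spec = classifier_spec()) {
  X_train <- unclass(X_train)
  classes <- sort(unique(y_train))
  if (length(classes) < 2) {
    stop("training fold contains a single class", call. = FALSE)
  }
  fit <- switch(spec$kind,
    svm_rbf = {
      gamma <- spec$gamma %||%
        (1 / (ncol(X_train) * max(mean(apply(X_train, 2, stats::var)), 1e-12)))
      e1071::svm(x = X_train, y = factor(y_train, levels = classes),
                 kernel = "radial", cost = spec$C, gamma = gamma,
                 scale = FALSE)
    },
    svm_linear = e1071::svm(x = X_train,
                            y = factor(y_train, levels = classes),
                            kernel = "linear", cost = spec$C, scale = FALSE),
    knn = list(X = X_train, y = y_train),
    rf = {
      df <- as.data.frame(X_train)
      names(df) <- paste0("f", seq_len(ncol(X_train)))
      ranger::ranger(x = df, y = factor(y_train, levels = classes),
                     num.trees = 200, seed = spec$seed, num.threads = 1)
    })
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 classes = classes, d = ncol(X_train)),
            class = "shallow_model")
}

knn_predict <- function(model, X_test, k) {
  Xtr <- model$fit$X
  ytr <- model$fit$y
  n <- nrow(X_test)
  out <- integer(n)
  # squared Euclidean distances via the expansion ||a-b||^2
  tr_sq <- rowSums(Xtr^2)
  for (i in seq_len(n)) {
    d2 <- tr_sq - 2 * as.vector(Xtr %*% X_test[i, ]) + sum(X_test[i, ]^2)
    nb <- order(d2, seq_along(d2))[seq_len(min(k, length(d2)))]
    votes <- table(factor(ytr[nb], levels = model$classes))
    out[i] <- model$classes[which.max(votes)]  # tie -> lowest class index
  }
  out
}

#' Predict labels with a fitted shallow classifier
#'
#' @param object a `shallow_model`.
#' @param X_test matrix with the training dimensionality, standardized
#'   with the training-fold statistics.
#' @param ... unused.
#' @return integer label vector.
#' @export
predict.shallow_model <- function(object, X_test, ...) {
  X_test <- unclass(X_test)
  if (ncol(X_test) != object$d) {
    stop_mismatch("feature dimension", object$d, ncol(X_test))
  }
  switch(object$kind,
    knn = knn_predict(object, X_test, object$spec$k_neighbors),
    rf = {
      df <- as.data.frame(X_test)
      names(df) <- paste0("f", seq_len(ncol(X_test)))
      as.integer(as.character(predict(object$fit, data = df)$predictions))
    },
    as.integer(as.character(predict(object$fit, X_test))))
}
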