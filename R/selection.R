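# Feature selection: four base strategies (PCA projection, chi-square
# scores, random-forest impurity importance, variance ranking) and the six
# pairwise intersections of their top-k sets, all defaulting to the 8:1
# reduction k = ceiling(D / 8).

BASE_METHODS <- c("pca", "chi2", "rf", "variance")

#' Default selection target dimension (8:1 reduction)
#'
#' @param D input feature dimension.
#' @return `ceiling(D / 8)`.
#' @export
default_k <- function(D) as.integer(ceiling(D / 8))

# deterministic descending ranking; ties broken by lower feature index
rank_desc <- function(scores) order(-scores, seq_along(scores))

# chi-square score per feature: columns min-max scaled to [0, 1], observed
# O_jc = class-wise column sum, expected E_jc = class prior * column total;
# terms with E = 0 contribute 0.
chi2_scores <- function(X, y) {
  n <- nrow(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
  classes <- sort(unique(y))
  tot <- colSums(Xs)
  sc <- numeric(ncol(X))
  for (c in classes) {
    O <- colSums(Xs[y == c, , drop = FALSE])
    E <- (sum(y == c) / n) * tot
    term <- ifelse(E > 0, (O - E)^2 / E, 0)
    sc <- sc + term
  }
  sc
}

rf_scores <- function(X, y, seed) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = df, y = factor(y), num.trees = 200,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  as.numeric(imp[paste0("f", seq_len(ncol(X)))])
}

#' Per-feature PCA importance
#'
#' Scores feature i as the sum over the leading k components of the
#' component's explained-variance ratio times the absolute loading of
#' feature i, giving PCA a per-feature ranking usable in intersections.
#'
#' @param X N x D feature matrix.
#' @param k number of leading components (default `default_k(D)`).
#' @return length-D vector of non-negative scores.
#' @export
pca_feature_importance <- function(X, k = default_k(ncol(X))) {
  X <- unclass(X)
  k <- min(k, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  V <- abs(pc$rotation[, seq_len(k), drop = FALSE])
  as.numeric(V %*% evr[seq_len(k)])
}

new_selection_result <- function(method, k, payload, d_in, fitted_on = NA,
                                 rankings = NULL) {
  structure(list(method = method, k = as.integer(k), payload = payload,
                 d_in = as.integer(d_in), fitted_on = fitted_on,
                 rankings = rankings),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  kind <- if (!is.null(x$payload$indices)) {
    sprintf("index subset of size %d", length(x$payload$indices))
  } else {
    sprintf("projection to %d components", ncol(x$payload$rotation))
  }
  cat(sprintf("selection_result [%s, k=%d]: %s (D=%d)\n",
              x$method, x$k, kind, x$d_in))
  invisible(x)
}

#' Fit a base feature selector
#'
#' `pca` fits a mean-centred projection onto the top-k eigenvectors of the
#' covariance; `chi2`, `rf` and `variance` rank features by score and keep
#' the top k (ties to the lower index). Labels are required for `chi2` and
#' `rf` and ignored otherwise.
#'
#' @param X N x D feature matrix (finite values).
#' @param y labels (integer vector), or `NULL` for unsupervised methods.
#' @param method one of `"pca"`, `"chi2"`, `"rf"`, `"variance"`.
#' @param k target dimension; defaults to the 8:1 reduction
#'   `ceiling(D / 8)`. Values above D are clipped with a warning.
#' @param seed seed (used by the random forest).
#' @param fitted_on optional identifier of the training fold.
#' @return a `selection_result` with an index or projection payload.
#' @export
select_features <- function(X, y = NULL, method = BASE_METHODS,
                            k = default_k(ncol(X)), seed = 1,
                            fitted_on = NA) {
  method <- match.arg(method)
  X <- unclass(X)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  D <- ncol(X)
  if (k > D) {
    warning(sprintf("k = %d exceeds feature dimension D = %d; clipped", k, D))
    k <- D
  }
  if (method %in% c("chi2", "rf") && is.null(y)) {
    stop(sprintf("method '%s' requires labels y", method), call. = FALSE)
  }
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$rotation))
    if (kk < k) {
      warning(sprintf("only %d principal components available; k clipped", kk))
    }
    payload <- list(center = pc$center,
                    rotation = pc$rotation[, seq_len(kk), drop = FALSE],
                    evr = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(kk)])
    return(new_selection_result("pca", kk, payload, D, fitted_on))
  }
  scores <- switch(method,
    chi2 = chi2_scores(X, y),
    rf = rf_scores(X, y, seed),
    variance = apply(X, 2, stats::var))
  idx <- sort(rank_desc(scores)[seq_len(k)])
  new_selection_result(method, k, list(indices = idx, scores = scores),
                       D, fitted_on)
}

#' Intersection of two base selectors' top-k sets
#'
#' Keeps the features ranked in the top k by both methods (PCA ranked via
#' [pca_feature_importance()]). If fewer than 2 features survive, the set
#' is back-filled from the union of the two top-k sets in order of mean
#' rank until it has 2 members. Both parent rankings are kept for audit.
#'
#' @param methodA,methodB distinct base method names.
#' @param X,y,k,seed,fitted_on as in [select_features()].
#' @return a `selection_result` with method `"A∩B"` and an index payload.
#' @export
intersect_selections <- function(methodA, methodB, X, y = NULL,
                                 k = default_k(ncol(X)), seed = 1,
                                 fitted_on = NA) {
  stopifnot(methodA %in% BASE_METHODS, methodB %in% BASE_METHODS)
  if (methodA == methodB) stop("methods must differ", call. = FALSE)
  X <- unclass(X)
  D <- ncol(X)
  k <- min(k, D)
  base_scores <- function(m) {
    switch(m,
      pca = pca_feature_importance(X, k),
      chi2 = chi2_scores(X, y),
      rf = rf_scores(X, y, seed),
      variance = apply(X, 2, stats::var))
  }
  rankA <- rank_desc(base_scores(methodA))
  rankB <- rank_desc(base_scores(methodB))
  topA <- rankA[seq_len(k)]
  topB <- rankB[seq_len(k)]
  S <- sort(intersect(topA, topB))
  if (length(S) < 2) {
    # mean rank position across the two full rankings
    posA <- order(rankA); posB <- order(rankB)
    cand <- setdiff(union(topA, topB), S)
    cand <- cand[order((posA[cand] + posB[cand]) / 2, cand)]
    S <- sort(c(S, cand[seq_len(2 - length(S))]))
  }
  new_selection_result(paste0(methodA, "∩", methodB), k,
                       list(indices = S), D, fitted_on,
                       rankings = list(A = rankA, B = rankB))
}

#' Enumerate the ten selection methods
#'
#' @return character vector of the 4 base methods and 6 pairwise
#'   intersections.
#' @export
selection_methods <- function() {
  pairs <- utils::combn(BASE_METHODS, 2)
  c(BASE_METHODS,
    apply(pairs, 2, function(p) paste0(p[1], "∩", p[2])))
}

# fit any of the ten methods by name
fit_selector <- function(name, X, y, k, seed, fitted_on = NA) {
  if (name %in% BASE_METHODS) {
    select_features(X, y, name, k, seed, fitted_on)
  } else {
    parts <- strsplit(name, "∩")[[1]]
    intersect_selections(parts[1], parts[2], X, y, k, seed, fitted_on)
  }
}

#' Apply a fitted selection to a feature matrix
#'
#' Index payloads subset columns; projection payloads compute
#' `(X - center) %*% rotation` using the training-fold centre (no
#' re-centering on held-out rows).
#'
#' @param X N x D matrix with the same D the selector was fitted on.
#' @param sel a `selection_result`.
#' @return reduced N x D' matrix.
#' @export
apply_selection <- function(X, sel) {
  stopifnot(inherits(sel, "selection_result"))
  X <- unclass(X)
  if (ncol(X) != sel$d_in) {
    stop(sprintf("feature dimension mismatch: selector fitted on D = %d, got %d",
                 sel$d_in, ncol(X)), call. = FALSE)
  }
  if (!is.null(sel$payload$indices)) {
    X[, sel$payload$indices, drop = FALSE]
  } else {
    sweep(X, 2, sel$payload$center, "-") %*% sel$payload$rotation
  }
}
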