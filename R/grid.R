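# The extractor x selector x classifier evaluation grid. Per fold the
# selector is fitted on training rows only, both partitions are
# transformed, standardized with training statistics, and the classifier
# is fitted and scored on the held-out fold — no statistic ever sees test
# rows.

#' Enumerate grid configurations
#'
#' Builds the Cartesian product in deterministic extractor-major order.
#' Presets: `"paper40"` = {gap, gmp} x 10 selectors x {svm_rbf, knn}
#' (40 configurations); `"full"` = {cbam, gap, gmp, prefinal} x 10 x
#' {svm_rbf, svm_linear, knn} (120); `"full+rf"` additionally admits the
#' random forest as a classifier (160).
#'
#' @param extractors,selectors,classifiers character vectors, or use
#'   `preset`.
#' @param preset `"paper40"`, `"full"` or `"full+rf"` (ignored when the
#'   three sets are given).
#' @return data.frame with columns extractor, selector, classifier.
#' @export
enumerate_grid <- function(extractors = NULL, selectors = NULL,
                           classifiers = NULL, preset = "paper40") {
  if (is.null(extractors)) {
    extractors <- switch(preset,
      paper40 = c("gap", "gmp"),
      full = c("cbam", "gap", "gmp", "prefinal"),
      `full+rf` = c("cbam", "gap", "gmp", "prefinal"),
      stop("unknown preset: ", preset, call. = FALSE))
    selectors <- selection_methods()
    classifiers <- switch(preset,
      paper40 = c("svm_rbf", "knn"),
      full = c("svm_rbf", "svm_linear", "knn"),
      `full+rf` = c("svm_rbf", "svm_linear", "knn", "rf"))
  }
  if (!length(extractors) || !length(selectors) || !length(classifiers)) {
    stop("extractor, selector and classifier sets must be non-empty",
         call. = FALSE)
  }
  bad <- setdiff(extractors, FEATURE_TAGS)
  if (length(bad)) stop("unknown extractor tag: ", bad[1], call. = FALSE)
  bad <- setdiff(selectors, selection_methods())
  if (length(bad)) stop("unknown selector: ", bad[1], call. = FALSE)
  bad <- setdiff(classifiers, c("svm_rbf", "svm_linear", "knn", "rf"))
  if (length(bad)) stop("unknown classifier: ", bad[1], call. = FALSE)
  grid <- expand.grid(classifier = classifiers, selector = selectors,
                      extractor = extractors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("extractor", "selector", "classifier")]
  rownames(grid) <- NULL
  grid
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  list(mu = mu, sd = sd)
}

standardize_apply <- function(X, st) {
  Z <- sweep(X, 2, st$mu, "-")
  nz <- st$sd > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, st$sd[nz], "/")
  Z[, !nz] <- 0  # constant columns left at 0
  Z
}

#' Run the deep-feature-engineering grid
#'
#' For every configuration and fold: fit the selector on the training
#' rows, transform train/test, standardize with training statistics, fit
#' the classifier and score the held-out fold. Base selector scores are
#' cached per (extractor, fold) so intersections reuse them.
#'
#' @param features named list of `feature_matrix` objects keyed by
#'   extractor tag (must cover every extractor in `configs`).
#' @param labels integer labels aligned with feature rows.
#' @param configs data.frame from [enumerate_grid()].
#' @param folds fold index list from [stratified_kfold()], or an integer
#'   number of folds (default 5).
#' @param k target selection dimension; default the 8:1 reduction of each
#'   extractor's D.
#' @param seed seed driving fold assignment, selector forests and
#'   classifier seeds.
#' @return object of class `grid_result`: data.frame `records` (one row
#'   per configuration with fold accuracies and mean metrics, ranked by
#'   mean accuracy, ties by F1 then config order) plus per-fold
#'   predictions.
#' @export
run_grid <- function(features, labels, configs = enumerate_grid(),
                     folds = 5, k = NULL, seed = 1) {
  need <- unique(configs$extractor)
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    stop("missing feature matrix for extractor tag: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.numeric(folds) && length(folds) == 1) {
    folds <- stratified_kfold(labels, folds, seed)
  }
  nf <- length(folds)
  n_classes <- length(unique(labels))

  # cache: per (extractor, fold) the scores of each base method and the
  # fitted PCA projection
  sel_cache <- new.env(parent = emptyenv())
  get_selector <- function(tag, method, fold_i, X_tr, y_tr, kk) {
    key <- paste(tag, method, fold_i, sep = "|")
    if (!is.null(sel_cache[[key]])) return(sel_cache[[key]])
    s <- fit_selector(method, X_tr, y_tr, kk,
                      seed = derive_seed(seed, "sel", tag, fold_i),
                      fitted_on = fold_i)
    sel_cache[[key]] <- s
    s
  }

  records <- NULL
  predictions <- list()
  for (ci in seq_len(nrow(configs))) {
    tag <- configs$extractor[ci]
    method <- configs$selector[ci]
    clf <- configs$classifier[ci]
    X <- unclass(features[[tag]])
    kk <- if (is.null(k)) default_k(ncol(X)) else min(k, ncol(X))
    fold_acc <- fold_prec <- fold_rec <- fold_f1 <- numeric(nf)
    preds <- vector("list", nf)
    for (fi in seq_len(nf)) {
      te <- folds[[fi]]
      tr <- setdiff(seq_along(labels), te)
      sel <- get_selector(tag, method, fi, X[tr, , drop = FALSE],
                          labels[tr], kk)
      Xtr <- apply_selection(X[tr, , drop = FALSE], sel)
      Xte <- apply_selection(X[te, , drop = FALSE], sel)
      st <- standardize_fit(Xtr)
      Xtr <- standardize_apply(Xtr, st)
      Xte <- standardize_apply(Xte, st)
      spec <- classifier_spec(clf,
                              seed = derive_seed(seed, "clf", tag, method,
                                                 clf, fi))
      model <- fit_classifier(Xtr, labels[tr], spec)
      yp <- predict(model, Xte)
      cm <- confusion_matrix(labels[te], yp, n_classes)
      rep <- suppressWarnings(classwise_metrics(cm))
      fold_acc[fi] <- rep$accuracy
      fold_prec[fi] <- rep$macro_precision
      fold_rec[fi] <- rep$macro_recall
      fold_f1[fi] <- rep$macro_f1
      preds[[fi]] <- data.frame(index = te, true = labels[te], pred = yp)
    }
    rec <- data.frame(extractor = tag, selector = method, classifier = clf,
                      accuracy = mean(fold_acc),
                      precision = mean(fold_prec),
                      recall = mean(fold_rec), f1 = mean(fold_f1),
                      stringsAsFactors = FALSE)
    rec$fold_accuracies <- I(list(fold_acc))
    records <- rbind(records, rec)
    predictions[[ci]] <- preds
  }
  records$config_order <- seq_len(nrow(records))
  ord <- order(-records$accuracy, -records$f1, records$config_order)
  records <- records[ord, ]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  structure(list(records = records, predictions = predictions[ord],
                 folds = folds, seed = seed, n_folds = nf),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, n = 10, ...) {
  r <- utils::head(x$records, n)
  cat(sprintf("grid_result: %d configurations, %d folds (top %d)\n",
              nrow(x$records), x$n_folds, nrow(r)))
  show <- r[, c("rank", "extractor", "selector", "classifier",
                "accuracy", "precision", "recall", "f1")]
  for (col in c("accuracy", "precision", "recall", "f1"))
    show[[col]] <- sprintf("%.2f", round_half_up(show[[col]], 2))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write grid results as CSV (table layout) and JSON (full fold detail)
#'
#' CSV columns match the conventional ranking-table headers: Rank,
#' Feature Layer, Selection, Classifier, Accuracy, Precision, Recall,
#' F1-Score (percentages at 2 decimals).
#'
#' @param result a `grid_result`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_grid_results <- function(result, csv_path = NULL, json_path = NULL) {
  r <- result$records
  if (!is.null(csv_path)) {
    out <- data.frame(Rank = r$rank, `Feature Layer` = r$extractor,
                      Selection = r$selector, Classifier = r$classifier,
                      Accuracy = sprintf("%.2f", round_half_up(r$accuracy, 2)),
                      Precision = sprintf("%.2f", round_half_up(r$precision, 2)),
                      Recall = sprintf("%.2f", round_half_up(r$recall, 2)),
                      `F1-Score` = sprintf("%.2f", round_half_up(r$f1, 2)),
                      check.names = FALSE)
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    detail <- lapply(seq_len(nrow(r)), function(i) {
      list(rank = r$rank[i], extractor = r$extractor[i],
           selector = r$selector[i], classifier = r$classifier[i],
           accuracy = r$accuracy[i], precision = r$precision[i],
           recall = r$recall[i], f1 = r$f1[i],
           fold_accuracies = r$fold_accuracies[[i]])
    })
    jsonlite::write_json(detail, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
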