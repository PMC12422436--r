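# Confusion-matrix metrics, stratified cross-validation and McNemar's
# paired test. Percentages are kept at full precision internally and
# rounded half-up to 2 decimals for display only.

#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  stopifnot(length(y_true) == length(y_pred))
  bad <- which(y_true < 1 | y_true > n_classes |
               y_pred < 1 | y_pred > n_classes)
  if (length(bad)) {
    stop(sprintf("label out of range [1, %d] at index %d", n_classes, bad[1]),
         call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Precision / recall / F1 from per-class counts
#'
#' One-vs-rest per class; 0/0 is defined as 0 (with a warning), so absent
#' classes in small folds never crash a run.
#'
#' @param tp,fp,fn vectors of per-class counts.
#' @return data.frame with precision, recall, f1 in percent (full
#'   precision).
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  safe_div <- function(num, den) {
    bad <- den == 0
    if (any(bad & num == 0)) {
      warning("0/0 in metric computation; defining the value as 0")
    }
    out <- ifelse(den > 0, num / den, 0)
    out
  }
  precision <- 100 * safe_div(tp, tp + fp)
  recall <- 100 * safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1)
}

#' Class-wise metrics report from a confusion matrix
#'
#' Per class c: TP = cm[c,c], FP = column sum - TP, FN = row sum - TP.
#' Macro averages are unweighted means over classes; accuracy is the
#' diagonal fraction. All values in percent.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param class_names optional class names.
#' @return object of class `classwise_report`: list with `per_class`
#'   data.frame, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `accuracy`.
#' @export
classwise_metrics <- function(cm, class_names = NULL) {
  if (length(cm) == 0 || sum(cm) == 0) stop("empty confusion matrix",
                                            call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  per <- metrics_from_counts(tp, fp, fn)
  if (!is.null(class_names)) per <- cbind(class = class_names, per)
  structure(list(per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 accuracy = 100 * sum(tp) / sum(cm)),
            class = "classwise_report")
}

#' @export
print.classwise_report <- function(x, ...) {
  per <- x$per_class
  for (col in c("precision", "recall", "f1")) per[[col]] <-
    sprintf("%.2f", round_half_up(per[[col]], 2))
  print(per, row.names = FALSE)
  cat(sprintf("macro P/R/F1: %.2f / %.2f / %.2f   accuracy: %.2f\n",
              round_half_up(x$macro_precision, 2),
              round_half_up(x$macro_recall, 2),
              round_half_up(x$macro_f1, 2),
              round_half_up(x$accuracy, 2)))
  invisible(x)
}

#' McNemar's paired test with continuity correction
#'
#' Compares two classifiers on the same samples through the discordant
#' counts b (A correct, B wrong) and c (A wrong, B correct):
#' `chi2 = (|b - c| - 1)^2 / (b + c)`, p from the chi-square distribution
#' with 1 df. When b + c = 0 the statistic is 0 and p = 1.
#'
#' @param y_true true labels.
#' @param pred_A,pred_B predicted labels from the two classifiers.
#' @return list with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(y_true, pred_A, pred_B) {
  if (length(y_true) != length(pred_A) || length(y_true) != length(pred_B)) {
    stop("prediction vectors must match y_true in length", call. = FALSE)
  }
  okA <- pred_A == y_true
  okB <- pred_B == y_true
  b <- sum(okA & !okB)
  c <- sum(!okA & okB)
  if (b + c == 0) return(list(statistic = 0, p_value = 1, b = b, c = c))
  stat <- (abs(b - c) - 1)^2 / (b + c)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c)
}

#' Stratified k-fold partition
#'
#' Shuffles each class with the seed and deals members round-robin, so
#' per-class counts differ by at most 1 across folds.
#'
#' @param y integer labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of k disjoint index vectors covering all samples.
#' @export
stratified_kfold <- function(y, k, seed = 1) {
  folds <- vector("list", k)
  for (i in seq_len(k)) folds[[i]] <- integer(0)
  with_seed(derive_seed(seed, "kfold"), {
    for (c in sort(unique(y))) {
      ci <- which(y == c)
      if (length(ci) < k) {
        stop(sprintf("class %s has %d members, fewer than k = %d folds",
                     c, length(ci), k), call. = FALSE)
      }
      ci <- sample(ci)
      for (j in seq_along(ci)) {
        f <- ((j - 1) %% k) + 1
        folds[[f]] <- c(folds[[f]], ci[j])
      }
    }
  })
  lapply(folds, sort)
}

#' Cross-validation summary
#'
#' Reports the mean and sample standard deviation of fold accuracies, the
#' mean +/- std interval used in conventional result tables
#' ("paper-style"), and a t-based 95% confidence interval
#' `mean +/- t_{0.975, n-1} * std / sqrt(n)`, clearly labeled apart.
#'
#' @param fold_accuracies numeric vector (>= 2 folds), in percent.
#' @return object of class `cv_summary`.
#' @export
cv_summary <- function(fold_accuracies) {
  n <- length(fold_accuracies)
  if (n < 2) stop("need at least 2 folds", call. = FALSE)
  m <- mean(fold_accuracies)
  s <- stats::sd(fold_accuracies)
  tq <- stats::qt(0.975, df = n - 1)
  structure(list(fold_accuracies = fold_accuracies, mean = m, sd = s,
                 interval_mean_sd = c(m - s, m + s),
                 ci95_t = c(m - tq * s / sqrt(n), m + tq * s / sqrt(n))),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  clip <- function(v) pmin(pmax(v, 0), 100)
  cat(sprintf("mean %.2f  sd %.2f\n", round_half_up(x$mean, 2),
              round_half_up(x$sd, 2)))
  cat(sprintf("mean±sd interval: [%.2f, %.2f]\n",
              round_half_up(clip(x$interval_mean_sd[1]), 2),
              round_half_up(clip(x$interval_mean_sd[2]), 2)))
  cat(sprintf("t-based 95%% CI:   [%.2f, %.2f]\n",
              round_half_up(clip(x$ci95_t[1]), 2),
              round_half_up(clip(x$ci95_t[2]), 2)))
  invisible(x)
}

#' Render a confusion matrix as a plain-text grid
#'
#' @param cm confusion matrix.
#' @param class_names optional class names.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
format_confusion <- function(cm, class_names = NULL) {
  cn <- class_names %||% paste0("C", seq_len(ncol(cm)))
  w <- max(nchar(cn), 6)
  header <- paste0(formatC("", width = w),
                   paste(formatC(cn, width = w), collapse = ""))
  lines <- c(header,
             vapply(seq_len(nrow(cm)), function(i) {
               paste0(formatC(cn[i], width = w),
                      paste(formatC(cm[i, ], width = w), collapse = ""))
             }, character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
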