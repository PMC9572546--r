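#' Confusion counts and threshold metrics
#'
#' Thresholds active-class confidences at `threshold` and computes the four
#' standard classification metrics from the confusion counts:
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall = TP/(TP+FN) and the
#' F1 score, the harmonic mean of precision and recall. When no compound is
#' predicted positive, precision (and hence F1) is reported as `NA` rather
#' than 0 so that averaging across folds is not silently deflated.
#'
#' @param labels Binary labels: logical, 0/1, or `"active"`/`"inactive"`.
#' @param confidences Active-class confidences in \[0, 1\].
#' @param threshold Classification threshold in (0, 1); default 0.5.
#' @param context Free-text tag (`"train_cv"`, `"test"`, ...).
#' @return A `metrics_report`: list with `counts` (TP, TN, FP, FN),
#'   `accuracy`, `precision`, `recall`, `f1`, `auc` (NA here; see
#'   [roc_auc()]), `context`.
#' @export
confusion_and_metrics <- function(labels, confidences, threshold = 0.5,
                                  context = "test") {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(confidences), length(y) > 0)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  pred <- confidences >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  metrics_from_counts(tp, tn, fp, fn, context = context)
}

#' Metrics from explicit confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer confusion counts.
#' @param context Free-text tag.
#' @return A `metrics_report`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn, context = "test") {
  n <- tp + tn + fp + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    accuracy = (tp + tn) / n, precision = precision, recall = recall,
    f1 = f1, auc = NA_real_, context = context
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s): acc %.3f  prec %s  rec %s  F1 %s  AUC %s\n",
              x$context, x$accuracy, fmt_na(x$precision), fmt_na(x$recall),
              fmt_na(x$f1), fmt_na(x$auc)))
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n",
              x$counts["TP"], x$counts["TN"], x$counts["FP"], x$counts["FN"]))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  l <- as.character(labels)
  if (!all(l %in% c("active", "inactive"))) {
    stop("labels must be logical, 0/1, or active/inactive", call. = FALSE)
  }
  as.integer(l == "active")
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen active
#' compound receives a higher confidence than a randomly chosen inactive one,
#' with ties counted one half. Computed from ranks, which is exactly the
#' pairwise comparison at any sample size.
#'
#' @param labels Binary labels (see [confusion_and_metrics()]).
#' @param confidences Numeric scores.
#' @return List with `auc` and `points`, a data frame of (FPR, TPR) curve
#'   points over all score thresholds.
#' @export
roc_auc <- function(labels, confidences) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(confidences))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC analysis", call. = FALSE)
  r <- rank(confidences, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(confidences, decreasing = TRUE)
  tpr <- cumsum(y[ord] == 1) / n1
  fpr <- cumsum(y[ord] == 0) / n0
  keep <- !duplicated(confidences[ord], fromLast = TRUE)
  points <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
  list(auc = auc, points = points)
}

#' Stratified k-fold assignment
#'
#' @param labels Binary labels.
#' @param folds Number of folds.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
make_folds <- function(labels, folds = 10, seed = 1) {
  y <- as_binary_labels(labels)
  if (folds > min(table(y))) {
    stop("folds exceeds the minority-class count", call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  fold
}

#' Cross-validated performance report
#'
#' Stratified k-fold cross-validation of an arbitrary fit/predict pair:
#' `trainer(X, y)` returns a fitted model and `predictor(model, X)` returns
#' active-class confidences. Per-fold metrics plus their mean and standard
#' deviation are reported; the fold assignment is deterministic given the
#' seed.
#'
#' @param matrix Feature matrix.
#' @param labels Binary labels.
#' @param trainer,predictor Fit and predict functions.
#' @param folds Number of stratified folds; default 10.
#' @param seed Integer seed.
#' @param threshold Classification threshold for the confusion metrics.
#' @return List with `per_fold` (data frame), `mean`, `sd` (named numeric over
#'   accuracy, precision, recall, f1, auc) and `fold_assignment`.
#' @export
crossval_report <- function(matrix, labels, trainer, predictor, folds = 10,
                            seed = 1, threshold = 0.5) {
  m <- as.matrix(matrix)
  y <- as_binary_labels(labels)
  fold <- make_folds(y, folds = folds, seed = seed)
  rows <- lapply(seq_len(folds), function(k) {
    tr <- fold != k; te <- fold == k
    model <- trainer(m[tr, , drop = FALSE], y[tr])
    conf <- predictor(model, m[te, , drop = FALSE])
    mr <- confusion_and_metrics(y[te], conf, threshold = threshold,
                                context = "train_cv")
    auc <- roc_auc(y[te], conf)$auc
    data.frame(fold = k, accuracy = mr$accuracy, precision = mr$precision,
               recall = mr$recall, f1 = mr$f1, auc = auc)
  })
  per_fold <- do.call(rbind, rows)
  stats_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[stats_cols], na.rm = TRUE),
       sd = vapply(per_fold[stats_cols], stats::sd, numeric(1), na.rm = TRUE),
       fold_assignment = fold)
}

#' Random-forest feature-importance ranking
#'
#' Impurity importances of the fitted random-forest base model, normalized to
#' sum to 1 and sorted descending; the top-ranked descriptors are the ones
#' the forest leans on most to separate actives from inactives.
#'
#' @param rf_model A fitted RF base model (from [train_base_models()]) or a
#'   `ranger` object grown with `importance = "impurity"`.
#' @param top_k Number of descriptors to report; default 10.
#' @return Data frame `descriptor, importance`, sorted descending, of length
#'   `min(top_k, n_features)`.
#' @export
feature_importance <- function(rf_model, top_k = 10) {
  if (inherits(rf_model, "qsar_base_model")) rf_model <- rf_model$fit
  if (!inherits(rf_model, "ranger")) {
    stop("feature_importance expects a fitted random-forest model", call. = FALSE)
  }
  imp <- rf_model$variable.importance
  if (is.null(imp)) stop("model was grown without impurity importance", call. = FALSE)
  imp <- pmax(imp, 0)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(imp, decreasing = TRUE)
  out <- data.frame(descriptor = names(imp)[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Permutation importance of features under any scoring model
#'
#' AUC drop when a single feature is permuted, averaged over `n_rep`
#' seeded permutations.
#'
#' @param predictor Function `(matrix) -> confidences`.
#' @param matrix Feature matrix.
#' @param labels Binary labels.
#' @param n_rep Permutations per feature; default 5.
#' @param seed Integer seed.
#' @return Data frame `descriptor, importance` sorted descending.
#' @export
permutation_importance <- function(predictor, matrix, labels, n_rep = 5, seed = 1) {
  m <- as.matrix(matrix)
  y <- as_binary_labels(labels)
  base_auc <- roc_auc(y, predictor(m))$auc
  set.seed(as.integer(seed))
  drops <- vapply(seq_len(ncol(m)), function(j) {
    mean(vapply(seq_len(n_rep), function(r) {
      mp <- m
      mp[, j] <- sample(mp[, j])
      base_auc - roc_auc(y, predictor(mp))$auc
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(descriptor = colnames(m), importance = drops,
                    stringsAsFactors = FALSE)
  out[order(out$importance, decreasing = TRUE), , drop = FALSE]
}
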