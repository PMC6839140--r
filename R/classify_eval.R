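## classify_eval: bagged-tree TN vs non-TN classification on signature
## features, ROC/AUC, and confusion-matrix metrics (per-class F1, MCC).

#' Train a bagged decision-tree ensemble for TN vs non-TN
#'
#' Bootstrap-aggregated binary classification trees with per-split feature
#' subsampling (`mtry = floor(sqrt(p))`). The per-tree node budget (a
#' maximum-leaf cap) is tuned by scanning candidate values 1..n-1 and
#' keeping the one with minimum out-of-bag error (ties broken toward the
#' smallest); a smaller scanning ensemble keeps the scan affordable and the
#' final forest is refit at the chosen cap. Fully deterministic given
#' `seed`.
#'
#' @param features samples x features numeric matrix (signature-restricted).
#' @param labels named factor/character with classes `TN` and `nonTN` (any
#'   two labels; the one named `"TN"` is the positive class).
#' @param seed integer RNG seed for the ensemble.
#' @param n_trees trees in the final forest (default 200).
#' @param n_trees_scan trees per candidate during the node scan (default 50).
#' @param node_grid candidate maximum-leaf values; default `1:(n-1)`.
#' @return list of class `tree_ensemble` with the fitted trees, the chosen
#'   `max_leaves`, the scan table, `oob_error` and training metadata.
#' @export
train_tree_ensemble <- function(features, labels, seed = 1L, n_trees = 200,
                                n_trees_scan = 50, node_grid = NULL) {
  if (is.null(rownames(features))) stop("features need sample rownames",
                                        call. = FALSE)
  lab <- labels[rownames(features)]
  if (anyNA(lab)) stop("labels must cover every sample", call. = FALSE)
  y <- as.integer(lab == "TN")
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < 2) stop("need >= 2 samples per class", call. = FALSE)
  n <- nrow(features)
  mtry <- max(1L, floor(sqrt(ncol(features))))
  if (is.null(node_grid)) node_grid <- seq_len(n - 1)

  X <- as.matrix(features)
  storage.mode(X) <- "double"
  scan <- data.frame(max_leaves = node_grid, oob_error = NA_real_)
  for (i in seq_along(node_grid)) {
    fit <- rf_fit_cpp(X, y, as.integer(n_trees_scan),
                      as.integer(node_grid[i]), as.integer(mtry),
                      as.double(seed))
    scan$oob_error[i] <- fit$oob_error
  }
  best <- node_grid[which.min(scan$oob_error)]  # which.min = first = smallest
  final <- rf_fit_cpp(X, y, as.integer(n_trees), as.integer(best),
                      as.integer(mtry), as.double(seed) + 1)
  structure(list(trees = final$trees, max_leaves = best, scan = scan,
                 oob_error = final$oob_error, oob_score = final$oob_score,
                 feature_names = colnames(features), mtry = mtry,
                 n_trees = n_trees, seed = seed),
            class = "tree_ensemble")
}

#' Per-sample TN vote fraction from a fitted ensemble
#'
#' @param ensemble a [train_tree_ensemble()] fit.
#' @param features samples x features matrix with the training feature
#'   columns.
#' @return named numeric vector of TN vote fractions in \[0, 1\].
#' @export
predict_scores <- function(ensemble, features) {
  miss <- setdiff(ensemble$feature_names, colnames(features))
  if (length(miss)) {
    stop("missing feature(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, ensemble$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  setNames(rf_predict_cpp(ensemble$trees, X), rownames(features))
}

#' ROC curve and AUC
#'
#' Thresholds sweep the observed scores; AUC is the trapezoid area, which
#' equals the Mann-Whitney probability of concordance with ties counted
#' one half.
#'
#' @param scores named numeric vector (higher = more TN-like).
#' @param labels labels over the scored samples; class `"TN"` (or the value
#'   of `positive`) is positive.
#' @param positive positive class label (default `"TN"`).
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "TN") {
  lab <- labels[names(scores)]
  if (anyNA(lab)) stop("labels must cover every scored sample", call. = FALSE)
  y <- lab == positive
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Confusion-matrix metrics: per-class F1, MCC, correct count
#'
#' Counts are in TN-positive orientation: `tp` = true TN called TN,
#' `fn` = true TN called non-TN, `fp` = true non-TN called TN, `tn` = true
#' non-TN called non-TN. F1 = 2 * precision * recall / (precision +
#' recall) with precision = TP/(TP+FP) and recall = TP/(TP+FN); the non-TN
#' F1 uses the class-swapped matrix. MCC = (tp*tn - fp*fn) /
#' sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)). Any metric with a zero denominator
#' is defined as 0 and flagged.
#'
#' @param tp,fn,fp,tn non-negative integer counts (total > 0).
#' @return list with `f1_tn`, `f1_nontn`, `mcc`, `n_correct`, `degenerate`
#'   flag, and 2-decimal display versions (`*_2dp`, half-up rounding).
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix is empty", call. = FALSE)
  f1 <- function(tp, fp, fn) {
    den <- 2 * tp + fp + fn
    if (den == 0) return(c(0, TRUE))
    c(2 * tp / den, FALSE)
  }
  a <- f1(tp, fp, fn)
  b <- f1(tn, fn, fp)
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den2)
  degenerate <- a[2] == 1 || b[2] == 1 || mcc_den2 == 0
  list(f1_tn = a[1], f1_nontn = b[1], mcc = mcc,
       n_correct = tp + tn, degenerate = degenerate,
       f1_tn_2dp = round_half_up(a[1]), f1_nontn_2dp = round_half_up(b[1]),
       mcc_2dp = round_half_up(mcc))
}

#' Build a 2x2 confusion matrix from predicted and true labels
#'
#' @param predicted,truth named vectors over the same samples; class
#'   `positive` is TN.
#' @param positive positive class label (default `"TN"`).
#' @return list with counts tp, fn, fp, tn.
#' @export
confusion_counts <- function(predicted, truth, positive = "TN") {
  truth <- truth[names(predicted)]
  if (anyNA(truth)) stop("truth must cover every predicted sample",
                         call. = FALSE)
  p <- predicted == positive
  t <- truth == positive
  list(tp = sum(p & t), fn = sum(!p & t), fp = sum(p & !t), tn = sum(!p & !t))
}
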