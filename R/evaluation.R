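# Confusion-based metrics, ROC/AUC, stratified cross-validation with
# full per-fold refitting, and independent-test evaluation.

#' Confusion counts from truth and predictions
#'
#' @param truth,predicted Label vectors ("positive"/"negative" or 0/1).
#' @return A `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, predicted) {
  t01 <- as_binary_labels(truth)
  p01 <- as_binary_labels(predicted)
  stopifnot(length(t01) == length(p01))
  structure(list(TP = sum(t01 == 1 & p01 == 1),
                 TN = sum(t01 == 0 & p01 == 0),
                 FP = sum(t01 == 0 & p01 == 1),
                 FN = sum(t01 == 1 & p01 == 0)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/n`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with
#' the convention MCC = 0 when any factor of the denominator is zero.
#' Sn/Sp/Acc are returned as fractions in \[0, 1\].
#'
#' @param counts A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return A list with `Sn`, `Sp`, `Acc`, `MCC` and the counts.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("no evaluated samples", call. = FALSE)
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  list(Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       Acc = (TP + TN) / n,
       MCC = if (denom == 0) 0 else (TP * TN - FP * FN) / denom,
       counts = counts)
}

#' ROC curve and AUC from decision scores
#'
#' The ROC is built by sweeping the threshold over the sorted unique
#' scores with ties grouped; the AUC is the trapezoidal area, which on
#' tie-free scores equals the Mann-Whitney probability that a random
#' positive outscores a random negative.
#'
#' @param labels Labels ("positive"/"negative" or 0/1); both classes
#'   required.
#' @param scores Finite numeric decision scores, higher = more positive.
#' @return List with `auc` and `roc`, a data.frame of (FPR, TPR) points.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(FPR = fpr, TPR = tpr))
}

make_report <- function(truth, predicted, scores, folds = NULL,
                        per_fold = NULL) {
  m <- compute_metrics(confusion_counts(truth, predicted))
  r <- roc_auc(truth, scores)
  structure(list(Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
                 AUC = r$auc, roc = r$roc, counts = m$counts,
                 per_fold = per_fold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.3f  AUC %.3f  (n = %d)\n",
    100 * x$Sn, 100 * x$Sp, 100 * x$Acc, x$MCC, x$AUC,
    x$counts$TP + x$counts$TN + x$counts$FP + x$counts$FN))
  invisible(x)
}

#' Stratified k-fold cross-validation of the fusion pipeline
#'
#' Samples are assigned to folds by a seeded shuffle within each class.
#' For every fold, all fitted components -- the class transition chains,
#' the selection masks, the normalization, and (when enabled) the SVM
#' grid search -- are refit on the training fold only, and the held-out
#' fold is scored. Pooled predictions give the headline confusion table;
#' per-fold metrics are also reported.
#'
#' @param set A `sample_set` with at least `k` samples per class.
#' @param config A [pipeline_config()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return A `metrics_report` with a `per_fold` data.frame.
#' @export
cross_validate <- function(set, config = pipeline_config(), k = 10,
                           seed = 1) {
  stopifnot(inherits(set, "sample_set"))
  labels <- set$samples$label
  if (min(set$n_positive, set$n_negative) < k) {
    stop("each class must have at least k = ", k, " samples", call. = FALSE)
  }
  fold <- stratified_folds(as_binary_labels(labels), k, seed)
  n <- length(labels)
  scores <- numeric(n); predicted <- character(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    train <- subset_samples(set, !te)
    test <- subset_samples(set, te)
    fit <- train_pipeline(train, config)
    pred <- predict(fit, test)
    scores[te] <- pred$score
    predicted[te] <- pred$label
    fm <- compute_metrics(confusion_counts(labels[te], pred$label))
    per_fold[[f]] <- data.frame(fold = f, Sn = fm$Sn, Sp = fm$Sp,
                                Acc = fm$Acc, MCC = fm$MCC)
  }
  make_report(labels, predicted, scores,
              per_fold = do.call(rbind, per_fold))
}

subset_samples <- function(set, keep) {
  new_sample_set(set$samples$sample_id[keep],
                 set$samples$sequence[keep],
                 set$samples$label[keep],
                 set$window_length)
}

#' Train on one set, evaluate on a disjoint set
#'
#' Single fit of the full pipeline on `train_set`, single evaluation on
#' `test_set` (metrics plus ROC/AUC from the decision scores).
#'
#' @param train_set,test_set `sample_set`s with the same window length.
#' @param config A [pipeline_config()].
#' @return A `metrics_report`.
#' @export
independent_test <- function(train_set, test_set,
                             config = pipeline_config()) {
  if (train_set$window_length != test_set$window_length) {
    stop("train and test window lengths differ (",
         train_set$window_length, " vs ", test_set$window_length, ")",
         call. = FALSE)
  }
  fit <- train_pipeline(train_set, config)
  pred <- predict(fit, test_set)
  make_report(test_set$samples$label, pred$label, pred$score)
}

#' Cross-validate the Markov likelihood-ratio baseline
#'
#' The baseline classifier: fit one transition chain per class on the
#' training fold, score held-out windows by [mm_score()], and call
#' positive iff the score exceeds 0.
#'
#' @inheritParams cross_validate
#' @param pseudocount Laplace smoothing for the chains.
#' @return A `metrics_report`.
#' @export
cross_validate_mm <- function(set, k = 10, pseudocount = 1, seed = 1) {
  labels <- set$samples$label
  if (min(set$n_positive, set$n_negative) < k) {
    stop("each class must have at least k = ", k, " samples", call. = FALSE)
  }
  fold <- stratified_folds(as_binary_labels(labels), k, seed)
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    te <- fold == f
    seqs <- set$samples$sequence
    pos <- fit_transition_model(seqs[!te & labels == "positive"],
                                pseudocount, "positive")
    neg <- fit_transition_model(seqs[!te & labels == "negative"],
                                pseudocount, "negative")
    scores[te] <- vapply(seqs[te], mm_score, numeric(1),
                         pos_model = pos, neg_model = neg)
  }
  predicted <- ifelse(scores > 0, "positive", "negative")
  make_report(labels, predicted, scores)
}
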