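# RBF-kernel SVM (libsvm via e1071) with power-of-two grid search over
# the cost C and kernel width gamma.

#' Default power-of-two grid for C and gamma
#'
#' `2^-5, 2^-4, ..., 2^5`: 11 values, so the default joint grid has
#' 11 x 11 = 121 candidate pairs.
#'
#' @return Numeric vector of 11 powers of two.
#' @export
default_grid <- function() 2^(-5:5)

# stratified fold assignment: seeded shuffle within class, folds sized
# within one sample of each other per class
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[rng$sample_int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# private RNG stream so that fold assignment never disturbs (or is
# disturbed by) the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  env$sample_int <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  env
}

#' Train an RBF-kernel SVM
#'
#' Fits a maximum-margin classifier with kernel
#' `exp(-gamma * ||u - v||^2)` on pre-normalized features. Features are
#' not rescaled here (the pipeline normalizes before training).
#'
#' @param X Numeric feature matrix.
#' @param y Labels ("positive"/"negative" or 0/1).
#' @param C Cost parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An `svm_decision` object with a [decision_scores()] method.
#' @export
train_svm <- function(X, y, C = 1, gamma = 0.125) {
  stopifnot(is.matrix(X), C > 0, gamma > 0)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- factor(ifelse(as_binary_labels(y) == 1, "positive", "negative"),
              levels = c("negative", "positive"))
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  fit <- e1071::svm(x = X, y = y, kernel = "radial", cost = C,
                    gamma = gamma, scale = FALSE)
  # libsvm orients the decision value toward the first class seen in the
  # training data; normalize so that positive scores mean 'positive'
  dv <- attr(predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1L], "positive")
  structure(list(fit = fit, flip = flip, C = C, gamma = gamma,
                 n_features = ncol(X)),
            class = "svm_decision")
}

#' Continuous decision scores of a trained SVM
#'
#' @param model An `svm_decision` from [train_svm()].
#' @param X Feature matrix with the training column layout.
#' @return Numeric vector of signed decision values; positive favors the
#'   methylated class.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "svm_decision"))
  if (ncol(X) != model$n_features) {
    stop("expected ", model$n_features, " feature columns, got ", ncol(X),
         call. = FALSE)
  }
  dv <- attr(predict(model$fit, X, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1L])
  if (model$flip) -s else s
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair of the grid by mean stratified
#' inner-cross-validation accuracy and returns the maximizer. Ties are
#' broken toward the smallest C, then the smallest gamma (the smoother
#' model).
#'
#' @param X Normalized feature matrix.
#' @param y Labels.
#' @param grid_C,grid_gamma Candidate values (default `2^(-5:5)` each).
#' @param inner_folds Number of stratified folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `C`, `gamma`, and `cv_table` (a data.frame of the
#'   full grid with mean CV accuracy per pair).
#' @export
grid_search_svm <- function(X, y, grid_C = default_grid(),
                            grid_gamma = default_grid(),
                            inner_folds = 5, seed = 1) {
  stopifnot(is.matrix(X), length(grid_C) > 0, length(grid_gamma) > 0)
  if (ncol(X) == 0L) stop("feature matrix has zero columns", call. = FALSE)
  y01 <- as_binary_labels(y)
  if (length(unique(y01)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  fold <- stratified_folds(y01, inner_folds, seed)
  cand <- expand.grid(C = sort(grid_C), gamma = sort(grid_gamma))
  cand <- cand[order(cand$C, cand$gamma), ]
  acc <- vapply(seq_len(nrow(cand)), function(j) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      te <- fold == f
      m <- train_svm(X[!te, , drop = FALSE], y01[!te],
                     C = cand$C[j], gamma = cand$gamma[j])
      pred <- decision_scores(m, X[te, , drop = FALSE]) > 0
      correct <- correct + sum(pred == (y01[te] == 1))
    }
    correct / length(y01)
  }, numeric(1))
  best <- which(acc >= max(acc))[1L]  # candidates ordered by (C, gamma)
  list(C = cand$C[best], gamma = cand$gamma[best],
       cv_table = data.frame(C = cand$C, gamma = cand$gamma,
                             accuracy = acc, row.names = NULL))
}
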