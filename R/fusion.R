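# Model-based feature selection (boosted-tree importances), block fusion,
# and min-max normalization.

# fixed ensemble settings for importance ranking; determinism is the
# requirement, so they are never exposed as tuning knobs
XGB_PARAMS <- list(nrounds = 100L, max_depth = 6L, eta = 0.3)

#' Rank feature importance with a boosted-tree ensemble
#'
#' Fits an XGBoost binary classifier (100 trees, depth 6, learning rate
#' 0.3, single thread) on one feature block and returns the per-column
#' impurity-gain importance; columns never used in a split (including
#' constant columns) get importance 0. Deterministic given the seed.
#'
#' @param block A `feature_block`.
#' @param labels Binary labels: factor/character with "positive" and
#'   "negative", or a 0/1 vector.
#' @param seed Integer seed for the ensemble.
#' @return Named non-negative numeric vector, one entry per column.
#' @export
rank_feature_importance <- function(block, labels, seed = 1) {
  stopifnot(inherits(block, "feature_block"))
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to rank features", call. = FALSE)
  }
  if (nrow(block$x) < 10L) {
    stop("need at least 10 samples to rank features", call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(block$x, label = y, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = XGB_PARAMS$max_depth,
                  eta = XGB_PARAMS$eta,
                  nthread = 1L, seed = as.integer(seed)),
    data = dtrain, nrounds = XGB_PARAMS$nrounds)
  imp <- xgboost::xgb.importance(model = booster)
  out <- setNames(numeric(ncol(block$x)), colnames(block$x))
  if (nrow(imp) > 0L) out[imp$Feature] <- imp$Gain
  out
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("positive", "negative")))
  as.numeric(labels == "positive")
}

#' Select a feature block's columns by importance threshold
#'
#' Under the default `mean_importance` rule, keeps every column whose
#' importance is at least the mean importance (ties at the threshold are
#' kept). `top_n` keeps the `n` highest-importance columns. If a rule
#' would keep nothing, the single highest-importance column is kept and
#' a message is emitted.
#'
#' @param block A `feature_block`.
#' @param labels Binary labels (see [rank_feature_importance()]).
#' @param rule "mean_importance" (default) or "top_n".
#' @param n Number of columns for the `top_n` rule.
#' @param seed Seed passed to the importance ranking.
#' @return A `selection_mask`: list with `block_name`, logical `keep`,
#'   `importances`, `rule`, `seed`.
#' @export
select_features <- function(block, labels,
                            rule = c("mean_importance", "top_n"),
                            n = NULL, seed = 1) {
  rule <- match.arg(rule)
  imp <- rank_feature_importance(block, labels, seed = seed)
  keep <- if (rule == "mean_importance") {
    imp >= mean(imp)
  } else {
    if (is.null(n)) stop("top_n rule requires n", call. = FALSE)
    rank(-imp, ties.method = "first") <= n
  }
  if (!any(keep)) {
    message("selection rule kept no columns for block '", block$block_name,
            "'; falling back to the single best column")
    keep[which.max(imp)] <- TRUE
  }
  structure(list(block_name = block$block_name, keep = unname(keep),
                 importances = imp, rule = rule, seed = seed),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask '%s': %d of %d columns kept (%s)\n",
              x$block_name, sum(x$keep), length(x$keep), x$rule))
  invisible(x)
}

#' Fuse feature blocks by masked concatenation
#'
#' Concatenates the kept columns of each block, in the given block order,
#' into a single block whose column names carry `block:` prefixes.
#'
#' @param blocks List of row-aligned `feature_block`s.
#' @param masks Optional list of `selection_mask`s, one per block
#'   (NULL keeps every column of every block).
#' @return A `feature_block` named "fused".
#' @export
fuse <- function(blocks, masks = NULL) {
  stopifnot(length(blocks) >= 1L)
  n <- nrow(blocks[[1L]]$x)
  parts <- lapply(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    if (nrow(blk$x) != n) {
      stop("block '", blk$block_name, "' has ", nrow(blk$x),
           " rows; expected ", n, call. = FALSE)
    }
    keep <- if (is.null(masks)) rep(TRUE, ncol(blk$x)) else {
      msk <- masks[[b]]
      if (length(msk$keep) != ncol(blk$x)) {
        stop("mask for block '", blk$block_name,
             "' does not match its column count", call. = FALSE)
      }
      msk$keep
    }
    x <- blk$x[, keep, drop = FALSE]
    colnames(x) <- paste0(blk$block_name, ":", colnames(x))
    x
  })
  feature_block("fused", do.call(cbind, parts))
}

#' Fit min-max normalization parameters on training features
#'
#' @param train A `feature_block` of training rows.
#' @return A `minmax_params` list with per-column `min` and `max`.
#' @export
fit_minmax <- function(train) {
  stopifnot(inherits(train, "feature_block"))
  structure(list(min = apply(train$x, 2L, min),
                 max = apply(train$x, 2L, max),
                 columns = colnames(train$x)),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' Rescales each column to `(x - min) / (max - min)` using the training
#' extrema; constant training columns map to 0 and out-of-range values
#' (new data beyond the training extrema) are clipped into \[0, 1\].
#'
#' @param params A `minmax_params` from [fit_minmax()].
#' @param block A `feature_block` with the same columns.
#' @return The normalized `feature_block`.
#' @export
apply_minmax <- function(params, block) {
  stopifnot(inherits(params, "minmax_params"), inherits(block, "feature_block"))
  if (ncol(block$x) != length(params$min) ||
      !identical(colnames(block$x), params$columns)) {
    stop("feature columns do not match the fitted normalization parameters",
         call. = FALSE)
  }
  rng <- params$max - params$min
  x <- sweep(block$x, 2L, params$min, "-")
  nonconst <- rng > 0
  x[, nonconst] <- sweep(x[, nonconst, drop = FALSE], 2L, rng[nonconst], "/")
  x[, !nonconst] <- 0
  x[x < 0] <- 0
  x[x > 1] <- 1
  feature_block(block$block_name, x)
}
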