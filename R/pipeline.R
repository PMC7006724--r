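# The fused model: encoders -> per-block selection -> fusion -> min-max
# -> RBF-SVM, with every fitted component frozen into the returned object.

#' Pipeline configuration
#'
#' Collects every tunable of the fusion pipeline with its default.
#'
#' @param encoders Encoder block list, in fusion order. Each element is an
#'   `encoder_spec` or the string "markov" for the Markov log-ratio block.
#'   Default: binary, ncp, kmer (k = 3), markov.
#' @param selection Where model-based feature selection runs:
#'   "before" fusion (default), "after", "both", or "none".
#' @param selection_rule "mean_importance" (default) or "top_n".
#' @param top_n Number of columns per block for the `top_n` rule.
#' @param pseudocount Laplace smoothing for the class transition chains.
#' @param markov_mode "log_ratio" (default) or "positive_prob".
#' @param C,gamma SVM parameters used when `grid_search = FALSE`;
#'   defaults 1.0 and 0.125.
#' @param grid_search If TRUE, tune (C, gamma) by stratified inner CV
#'   over `grid_C x grid_gamma` instead of using the fixed values.
#' @param grid_C,grid_gamma Candidate grids (default `2^(-5:5)`).
#' @param inner_folds Folds for the grid search (default 5).
#' @param seed Seed governing feature selection and fold assignment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(encoders = list(encoder_spec("binary"),
                                            encoder_spec("ncp"),
                                            encoder_spec("kmer", k = 3),
                                            "markov"),
                            selection = c("before", "after", "both", "none"),
                            selection_rule = c("mean_importance", "top_n"),
                            top_n = NULL,
                            pseudocount = 1,
                            markov_mode = c("log_ratio", "positive_prob"),
                            C = 1, gamma = 0.125,
                            grid_search = FALSE,
                            grid_C = default_grid(),
                            grid_gamma = default_grid(),
                            inner_folds = 5,
                            seed = 1) {
  structure(list(encoders = encoders,
                 selection = match.arg(selection),
                 selection_rule = match.arg(selection_rule),
                 top_n = top_n,
                 pseudocount = pseudocount,
                 markov_mode = match.arg(markov_mode),
                 C = C, gamma = gamma,
                 grid_search = grid_search,
                 grid_C = grid_C, grid_gamma = grid_gamma,
                 inner_folds = inner_folds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# encode all configured blocks for a sample set, using already-fitted
# class transition models for the markov block
encode_blocks <- function(set, config, pos_model, neg_model) {
  lapply(config$encoders, function(spec) {
    if (identical(spec, "markov")) {
      x <- t(vapply(set$samples$sequence, function(s) {
        markov_features(s, pos_model, neg_model, mode = config$markov_mode)
      }, numeric(set$window_length - 1L)))
      rownames(x) <- set$samples$sample_id
      colnames(x) <- paste0("pair", seq_len(ncol(x)))
      feature_block("markov", x)
    } else {
      encode_dataset(set, spec)
    }
  })
}

#' Train the fusion pipeline
#'
#' Fits, on the given training set only: the class-conditional transition
#' chains, one selection mask per feature block (in "before"/"both"
#' modes), a post-fusion mask ("after"/"both"), the min-max
#' normalization, optionally the SVM grid search, and the final RBF-SVM.
#'
#' @param set A `sample_set` with both classes present.
#' @param config A [pipeline_config()].
#' @return A `trained_pipeline` holding every frozen component plus the
#'   chosen `(C, gamma)`, the stored training accuracy, and the training
#'   window length.
#' @export
train_pipeline <- function(set, config = pipeline_config()) {
  stopifnot(inherits(set, "sample_set"))
  if (set$n_positive == 0L || set$n_negative == 0L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  labels <- set$samples$label
  pos_model <- fit_transition_model(
    set$samples$sequence[labels == "positive"],
    pseudocount = config$pseudocount, class_tag = "positive")
  neg_model <- fit_transition_model(
    set$samples$sequence[labels == "negative"],
    pseudocount = config$pseudocount, class_tag = "negative")

  blocks <- encode_blocks(set, config, pos_model, neg_model)
  masks <- NULL
  if (config$selection %in% c("before", "both")) {
    masks <- lapply(blocks, select_features, labels = labels,
                    rule = config$selection_rule, n = config$top_n,
                    seed = config$seed)
  }
  fused <- fuse(blocks, masks)
  mask_after <- NULL
  if (config$selection %in% c("after", "both")) {
    mask_after <- select_features(fused, labels,
                                  rule = config$selection_rule,
                                  n = config$top_n, seed = config$seed)
    fused <- fuse(list(fused), list(mask_after))
    # strip the extra "fused:" prefix added by the second fuse pass
    colnames(fused$x) <- sub("^fused:", "", colnames(fused$x))
  }
  norm <- fit_minmax(fused)
  X <- apply_minmax(norm, fused)$x

  if (isTRUE(config$grid_search)) {
    gs <- grid_search_svm(X, labels, grid_C = config$grid_C,
                          grid_gamma = config$grid_gamma,
                          inner_folds = config$inner_folds,
                          seed = config$seed)
    C <- gs$C; gamma <- gs$gamma; cv_table <- gs$cv_table
  } else {
    C <- config$C; gamma <- config$gamma; cv_table <- NULL
  }
  svm <- train_svm(X, labels, C = C, gamma = gamma)
  train_acc <- mean((decision_scores(svm, X) > 0) == (labels == "positive"))

  structure(list(config = config,
                 window_length = set$window_length,
                 pos_model = pos_model, neg_model = neg_model,
                 masks = masks, mask_after = mask_after,
                 norm = norm, svm = svm,
                 C = C, gamma = gamma, grid_table = cv_table,
                 training_accuracy = train_acc,
                 n_train = nrow(set$samples)),
            class = "trained_pipeline")
}

#' @export
print.trained_pipeline <- function(x, ...) {
  cat(sprintf(paste0(
    "trained_pipeline: %d training samples, window %d bp\n",
    "  fused dimension %d, C = %g, gamma = %g, training accuracy %.3f\n"),
    x$n_train, x$window_length, length(x$norm$min), x$C, x$gamma,
    x$training_accuracy))
  invisible(x)
}

#' Predict methylation labels and decision scores
#'
#' Applies the frozen pipeline (encoders, masks, fusion, clipped min-max,
#' SVM decision function) to new samples. A sample is called positive iff
#' its decision score exceeds 0.
#'
#' @param object A `trained_pipeline`.
#' @param set A `sample_set` whose window length matches the training
#'   window.
#' @param ... Unused.
#' @return A data.frame with `sample_id`, `score`, `label`, in input
#'   order.
#' @export
predict.trained_pipeline <- function(object, set, ...) {
  stopifnot(inherits(set, "sample_set"))
  if (set$window_length != object$window_length) {
    stop("window length ", set$window_length,
         " does not match the pipeline's training window ",
         object$window_length, call. = FALSE)
  }
  blocks <- encode_blocks(set, object$config, object$pos_model,
                          object$neg_model)
  fused <- fuse(blocks, object$masks)
  if (!is.null(object$mask_after)) {
    fused <- fuse(list(fused), list(object$mask_after))
    colnames(fused$x) <- sub("^fused:", "", colnames(fused$x))
  }
  X <- apply_minmax(object$norm, fused)$x
  score <- decision_scores(object$svm, X)
  data.frame(sample_id = set$samples$sample_id,
             score = score,
             label = ifelse(score > 0, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Choose a trimming radius by cross-validated accuracy
#'
#' Evaluates [cross_validate()] accuracy of the pipeline at each
#' candidate symmetric trimming radius and returns the best (ties go to
#' the smaller radius, i.e. the shorter window).
#'
#' @param set A full-width `sample_set`.
#' @param config A [pipeline_config()].
#' @param radii Candidate radii (default 10:20 for 41-bp windows).
#' @param k Folds used for the evaluation (default 5).
#' @param seed Fold seed.
#' @return List with `radius`, and `table` of per-radius accuracy.
#' @export
optimize_window_radius <- function(set, config = pipeline_config(),
                                   radii = 10:20, k = 5, seed = 1) {
  max_r <- (set$window_length - 1L) %/% 2L
  radii <- radii[radii >= 1 & radii <= max_r]
  if (length(radii) == 0L) stop("no valid radii to evaluate", call. = FALSE)
  acc <- vapply(radii, function(r) {
    cross_validate(trim_to_window(set, r), config, k = k, seed = seed)$Acc
  }, numeric(1))
  best <- radii[which.max(acc)]  # which.max takes the first (smallest) tie
  list(radius = best,
       table = data.frame(radius = radii, accuracy = acc))
}
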