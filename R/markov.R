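# Position-specific first-order Markov chains: one 4x4 row-stochastic
# transition matrix per adjacent position pair, fitted per class. The
# per-sequence feature is the vector of (log-ratio) transition
# probabilities; summing the log-ratios gives the likelihood-ratio
# baseline classifier.

#' Fit a position-specific first-order Markov transition model
#'
#' For each adjacent position pair `i in 1..L-1`, estimates the 4x4
#' row-stochastic matrix `P^i[x, y] = Pr(base_{i+1} = y | base_i = x)`
#' with Laplace smoothing:
#' `(count(x at i, y at i+1) + alpha) / (count(x at i) + 4 * alpha)`.
#'
#' @param sequences Character vector of equal-length A/C/G/T sequences.
#' @param pseudocount Smoothing constant `alpha >= 0` (default 1).
#' @param class_tag Optional label ("positive"/"negative") carried along.
#' @return A `transition_model`: list with `window_length`, `P`
#'   (a `4 x 4 x (L-1)` array), `pseudocount`, `class_tag`.
#' @export
fit_transition_model <- function(sequences, pseudocount = 1,
                                 class_tag = NULL) {
  if (length(sequences) == 0L) {
    stop("cannot fit a transition model on an empty sample list",
         call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  L <- nchar(sequences[1L])
  if (any(nchar(sequences) != L)) {
    stop("sequences must have uniform length", call. = FALSE)
  }
  if (L < 2L) stop("window length must be >= 2", call. = FALSE)
  m <- seq_to_int_matrix(sequences)
  P <- array(NA_real_, dim = c(4L, 4L, L - 1L),
             dimnames = list(DNA_BASES, DNA_BASES, NULL))
  for (i in seq_len(L - 1L)) {
    counts <- matrix(
      tabulate(4L * (m[, i] - 1L) + m[, i + 1L], nbins = 16L),
      nrow = 4L, byrow = TRUE)
    P[, , i] <- (counts + pseudocount) /
      (rowSums(counts) + 4 * pseudocount)
  }
  structure(list(window_length = L, P = P, pseudocount = pseudocount,
                 class_tag = class_tag),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "transition_model: %d position pairs (L = %d), pseudocount %g%s\n",
    dim(x$P)[3L], x$window_length, x$pseudocount,
    if (!is.null(x$class_tag)) paste0(", class '", x$class_tag, "'") else ""))
  invisible(x)
}

# per-pair transition probabilities of one sequence under one model
lookup_transitions <- function(idx, model) {
  L <- length(idx)
  i <- seq_len(L - 1L)
  model$P[cbind(idx[i], idx[i + 1L], i)]
}

#' Markov feature vector of a sequence
#'
#' For an L-bp window, the `L - 1` per-position transition probabilities
#' under class-conditional chains. In `log_ratio` mode (the default)
#' component `i` is `log(P+^i / P-^i)`, the per-transition log-likelihood
#' ratio between the positive and negative chains; in `positive_prob`
#' mode it is the positive-chain probability alone. No initial-state
#' probability enters the feature.
#'
#' @param sequence DNA string whose length matches the fitted models.
#' @param pos_model `transition_model` fitted on the positive class.
#' @param neg_model `transition_model` fitted on the negative class
#'   (ignored in `positive_prob` mode, may be NULL there).
#' @param mode "log_ratio" or "positive_prob".
#' @return Numeric vector of length `L - 1`.
#' @export
markov_features <- function(sequence, pos_model, neg_model = NULL,
                            mode = c("log_ratio", "positive_prob")) {
  mode <- match.arg(mode)
  check_acgt(sequence)
  L <- nchar(sequence)
  if (L != pos_model$window_length) {
    stop("sequence length ", L, " does not match model window length ",
         pos_model$window_length, call. = FALSE)
  }
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES)
  p_pos <- lookup_transitions(idx, pos_model)
  if (mode == "positive_prob") {
    return(p_pos)
  }
  if (is.null(neg_model)) {
    stop("log_ratio mode requires a negative-class model", call. = FALSE)
  }
  if (neg_model$window_length != L) {
    stop("sequence length ", L, " does not match model window length ",
         neg_model$window_length, call. = FALSE)
  }
  p_neg <- lookup_transitions(idx, neg_model)
  if (any(p_pos == 0) || any(p_neg == 0)) {
    stop("zero transition probability encountered; refit the models with ",
         "pseudocount > 0", call. = FALSE)
  }
  log(p_pos) - log(p_neg)
}

#' Markov-chain log-likelihood-ratio score
#'
#' The baseline classifier score: the sum over all adjacent position
#' pairs of `log(P+^i / P-^i)`, i.e. the log of the ratio of the two
#' chains' transition-probability products. Positive scores favor the
#' methylated class; classify positive iff `score > 0`.
#'
#' @inheritParams markov_features
#' @return A single numeric log-likelihood ratio.
#' @export
mm_score <- function(sequence, pos_model, neg_model) {
  sum(markov_features(sequence, pos_model, neg_model, mode = "log_ratio"))
}
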