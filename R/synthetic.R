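# Synthetic benchmark generator: fixed-length windows with a forced
# center adenine and class-conditional, position-specific first-order
# Markov structure of controllable strength, plus the exact Bayes
# classifier for calibration.

default_signal_positions <- function(L) {
  center <- (L + 1L) %/% 2L
  # transition pairs into/out of the center are excluded so that forcing
  # the center base to 'A' after sampling leaves the planted rows exact
  cand <- setdiff(seq_len(L - 1L), c(center - 1L, center))
  d <- pmin(abs(cand - center), abs(cand + 1L - center))
  sort(head(cand[order(d, cand)], 5L))
}

#' Synthetic-benchmark generator configuration
#'
#' Negatives are drawn from a uniform first-order chain; positives from
#' the same chain with selected transition rows perturbed toward a
#' designated successor base by mixing weight `effect_size`, so that the
#' two classes differ only in position-specific transition structure.
#' An optional `composition_bias` additionally tilts the positive
#' class's remaining rows toward adenine, feeding marginal-composition
#' signal to the k-mer/NCP blocks.
#'
#' @param n_positive,n_negative Class sizes.
#' @param window_length Odd window length L (default 41).
#' @param effect_size Mixing weight in \[0, 1\] of the point-mass
#'   perturbation applied to the signal rows (0 = null generator).
#' @param signal_positions Position-pair indices (subset of `1..L-1`,
#'   excluding the two pairs touching the center) carrying the signal;
#'   default: the 5 valid pairs nearest the center.
#' @param composition_bias Mixing weight in \[0, 1\) toward adenine on
#'   the positive class's non-signal rows (default 0).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_positive, n_negative,
                             window_length = 41,
                             effect_size = 0.5,
                             signal_positions = NULL,
                             composition_bias = 0,
                             seed = 1) {
  L <- as.integer(window_length)
  if (L %% 2L == 0L || L < 5L) {
    stop("window_length must be odd and >= 5", call. = FALSE)
  }
  if (effect_size < 0 || effect_size > 1) {
    stop("effect_size must be in [0, 1]", call. = FALSE)
  }
  if (composition_bias < 0 || composition_bias >= 1) {
    stop("composition_bias must be in [0, 1)", call. = FALSE)
  }
  center <- (L + 1L) %/% 2L
  if (is.null(signal_positions)) {
    signal_positions <- default_signal_positions(L)
  }
  signal_positions <- as.integer(signal_positions)
  if (any(signal_positions < 1L | signal_positions > L - 1L)) {
    stop("signal_positions must lie in [1, L-1]", call. = FALSE)
  }
  if (any(signal_positions %in% c(center - 1L, center))) {
    stop("signal_positions must exclude the pairs touching the center (",
         center - 1L, " and ", center, ")", call. = FALSE)
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 window_length = L,
                 effect_size = effect_size,
                 signal_positions = signal_positions,
                 composition_bias = composition_bias,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# true class-conditional chains as transition_model objects
true_chains <- function(config) {
  L <- config$window_length
  center <- (L + 1L) %/% 2L
  base <- matrix(0.25, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  Pn <- array(base, dim = c(4L, 4L, L - 1L),
              dimnames = list(DNA_BASES, DNA_BASES, NULL))
  Pp <- Pn
  eps <- config$effect_size
  for (i in config$signal_positions) {
    for (x in 1:4) {
      favored <- x %% 4L + 1L  # A->C, C->G, G->T, T->A
      row <- (1 - eps) * 0.25 + eps * (seq_len(4L) == favored)
      Pp[x, , i] <- row
    }
  }
  beta <- config$composition_bias
  if (beta > 0) {
    plain <- setdiff(seq_len(L - 1L),
                     c(config$signal_positions, center - 1L, center))
    for (i in plain) {
      Pp[, , i] <- (1 - beta) * 0.25 + beta * outer(rep(1, 4L), c(1, 0, 0, 0))
    }
  }
  list(
    positive = structure(list(window_length = L, P = Pp, pseudocount = 0,
                              class_tag = "positive"),
                         class = "transition_model"),
    negative = structure(list(window_length = L, P = Pn, pseudocount = 0,
                              class_tag = "negative"),
                         class = "transition_model"))
}

sample_from_chain <- function(n, model) {
  L <- model$window_length
  m <- matrix(0L, n, L)
  m[, 1L] <- sample.int(4L, n, replace = TRUE)  # uniform initial state
  for (i in seq_len(L - 1L)) {
    for (x in 1:4) {
      sel <- m[, i] == x
      if (any(sel)) {
        m[sel, i + 1L] <- sample.int(4L, sum(sel), replace = TRUE,
                                     prob = model$P[x, , i])
      }
    }
  }
  m
}

#' Generate a synthetic benchmark dataset
#'
#' Draws both classes from their configured chains, forces the center
#' position to adenine, and returns the sample set together with the
#' true class-conditional chains for oracle computations.
#'
#' @param config A [generator_config()].
#' @return List with `set` (a `sample_set`), `pos_model` and `neg_model`
#'   (the true `transition_model`s).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  chains <- true_chains(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  center <- (config$window_length + 1L) %/% 2L
  mp <- sample_from_chain(config$n_positive, chains$positive)
  mn <- sample_from_chain(config$n_negative, chains$negative)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  mp[, center] <- 1L
  mn[, center] <- 1L
  to_seq <- function(m) {
    apply(m, 1L, function(r) paste0(DNA_BASES[r], collapse = ""))
  }
  ids <- c(sprintf("pos_%d", seq_len(config$n_positive)),
           sprintf("neg_%d", seq_len(config$n_negative)))
  set <- new_sample_set(
    ids, c(to_seq(mp), to_seq(mn)),
    rep(c("positive", "negative"),
        c(config$n_positive, config$n_negative)),
    config$window_length)
  list(set = set, pos_model = chains$positive, neg_model = chains$negative)
}

# exact log-likelihood ratio under the true chains; transitions touching
# the forced center are excluded (their true ratio is 1 by construction)
true_llr <- function(m, config, chains) {
  L <- config$window_length
  center <- (L + 1L) %/% 2L
  pairs <- setdiff(seq_len(L - 1L), c(center - 1L, center))
  llr <- numeric(nrow(m))
  for (i in pairs) {
    pp <- chains$positive$P[cbind(m[, i], m[, i + 1L], i)]
    pn <- chains$negative$P[cbind(m[, i], m[, i + 1L], i)]
    llr <- llr + log(pp) - log(pn)  # -Inf allowed when pp = 0
  }
  llr
}

#' Monte-Carlo estimate of the generator's Bayes accuracy
#'
#' Draws fresh samples from the true chains and classifies them with the
#' exact log-likelihood ratio (positive iff LLR > 0; ties count 1/2).
#' This is the best accuracy any classifier can achieve on the
#' configuration.
#'
#' @param config A [generator_config()].
#' @param n_mc Monte-Carlo sample size (>= 100; default 10000), split
#'   evenly between the classes.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `accuracy` and its binomial standard error `se`.
#' @export
bayes_accuracy <- function(config, n_mc = 10000, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  if (n_mc < 100) stop("n_mc must be >= 100", call. = FALSE)
  half <- ceiling(n_mc / 2)
  chains <- true_chains(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  mp <- sample_from_chain(half, chains$positive)
  mn <- sample_from_chain(half, chains$negative)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  center <- (config$window_length + 1L) %/% 2L
  mp[, center] <- 1L; mn[, center] <- 1L
  lp <- true_llr(mp, config, chains)
  ln <- true_llr(mn, config, chains)
  correct <- sum(lp > 0) + 0.5 * sum(lp == 0) +
    sum(ln < 0) + 0.5 * sum(ln == 0)
  acc <- correct / (2 * half)
  list(accuracy = acc, se = sqrt(acc * (1 - acc) / (2 * half)))
}
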