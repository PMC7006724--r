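# Deterministic per-sequence feature encoders. Each returns a plain numeric
# vector; encode_dataset() stacks them into a named feature_block matrix.

check_acgt <- function(sequence) {
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    stop("non-ACGT character '", substr(sequence, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
}

#' One-hot binary encoding of a DNA sequence
#'
#' Each position contributes a 4-bit indicator (A=\[1,0,0,0\], C=\[0,1,0,0\],
#' G=\[0,0,1,0\], T=\[0,0,0,1\]), giving a `4 * m` vector for an m-nucleotide
#' sequence.
#'
#' @param sequence DNA string over A/C/G/T.
#' @return Numeric vector of length `4 * nchar(sequence)`.
#' @export
encode_binary <- function(sequence) {
  check_acgt(sequence)
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES)
  m <- length(idx)
  v <- numeric(4L * m)
  v[4L * (seq_len(m) - 1L) + idx] <- 1
  names(v) <- paste0("pos", rep(seq_len(m), each = 4L), "_", DNA_BASES)
  v
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Each position contributes three binary indicators: ring structure
#' (1 for purines A/G), hydrogen bonding (1 for the weakly bonded A/T
#' pair), and functional group (1 for the amino bases A/C). So A=(1,1,1),
#' C=(0,0,1), G=(1,0,0), T=(0,1,0).
#'
#' @param sequence DNA string over A/C/G/T.
#' @return Numeric vector of length `3 * nchar(sequence)`.
#' @export
encode_ncp <- function(sequence) {
  check_acgt(sequence)
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES)
  v <- as.numeric(t(NCP_TABLE[idx, , drop = FALSE]))
  names(v) <- paste0("pos", rep(seq_along(idx), each = 3L), "_",
                     c("a", "b", "c"))
  v
}

# all 4^k k-mers in lexicographic order over A < C < G < T
kmer_alphabet <- function(k) {
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  words <- do.call(paste0, grid[rev(seq_len(k))])
  sort(words)
}

#' k-mer composition encoding
#'
#' Frequencies of the `4^k` possible words among the `L - k + 1`
#' overlapping windows of the sequence; components sum to 1. Columns are
#' in lexicographic order over A < C < G < T.
#'
#' @param sequence DNA string of length `L >= k`.
#' @param k Word length, 1 to 4 (default 3).
#' @return Numeric vector of length `4^k`.
#' @export
encode_kmer <- function(sequence, k = 3) {
  check_acgt(sequence)
  k <- as.integer(k)
  if (k < 1L || k > 4L) stop("k must be in [1, 4]", call. = FALSE)
  L <- nchar(sequence)
  if (L < k) stop("sequence length ", L, " < k = ", k, call. = FALSE)
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  n_win <- L - k + 1L
  # base-4 code of each window, most significant digit first (lexicographic)
  code <- integer(n_win)
  for (j in seq_len(k)) {
    code <- code * 4L + idx[j:(j + n_win - 1L)]
  }
  counts <- tabulate(code + 1L, nbins = 4L^k)
  setNames(counts / n_win, kmer_alphabet(k))
}

#' Enhanced nucleic acid composition (ENAC) encoding
#'
#' For each of the `L - w + 1` sliding windows of width `w`, the four
#' nucleotide frequencies within the window (each window's four values
#' sum to 1), concatenated window by window.
#'
#' @param sequence DNA string of length `L >= window`.
#' @param window Sliding-window width (default 5).
#' @return Numeric vector of length `4 * (L - window + 1)`.
#' @export
encode_enac <- function(sequence, window = 5) {
  check_acgt(sequence)
  w <- as.integer(window)
  L <- nchar(sequence)
  if (w < 2L || w > L) {
    stop("window must be in [2, ", L, "], got ", w, call. = FALSE)
  }
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES)
  n_win <- L - w + 1L
  v <- numeric(4L * n_win)
  for (s in seq_len(n_win)) {
    v[4L * (s - 1L) + seq_len(4L)] <-
      tabulate(idx[s:(s + w - 1L)], nbins = 4L) / w
  }
  names(v) <- paste0("win", rep(seq_len(n_win), each = 4L), "_", DNA_BASES)
  v
}

#' Encoder specification
#'
#' @param name One of "binary", "ncp", "kmer", "enac".
#' @param k Word length for the k-mer encoder (1-4, default 3).
#' @param window Sliding-window width for the ENAC encoder (default 5).
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(name = c("binary", "ncp", "kmer", "enac"),
                         k = 3, window = 5) {
  name <- match.arg(name)
  if (name == "kmer" && (k < 1 || k > 4)) {
    stop("k must be in [1, 4]", call. = FALSE)
  }
  structure(list(name = name, k = as.integer(k),
                 window = as.integer(window)),
            class = "encoder_spec")
}

#' Encode every sample in a set with one encoder
#'
#' @param set A `sample_set`.
#' @param spec An `encoder_spec` (or an encoder name, for defaults).
#' @return A `feature_block`: list with `block_name` and `x`, an
#'   `n x d` matrix whose rows follow the sample order and whose column
#'   names label the features.
#' @export
encode_dataset <- function(set, spec) {
  stopifnot(inherits(set, "sample_set"))
  if (is.character(spec)) spec <- encoder_spec(spec)
  enc <- switch(spec$name,
    binary = encode_binary,
    ncp    = encode_ncp,
    kmer   = function(s) encode_kmer(s, k = spec$k),
    enac   = function(s) encode_enac(s, window = spec$window)
  )
  seqs <- set$samples$sequence
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch(enc(seqs[i]), error = function(e) {
      stop("encoding failed for sample '", set$samples$sample_id[i], "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  x <- do.call(rbind, rows)
  rownames(x) <- set$samples$sample_id
  feature_block(spec$name, x)
}

#' Construct a feature block
#'
#' @param block_name Name of the producing encoder.
#' @param x Numeric matrix, rows aligned to a sample set, named columns.
#' @return A `feature_block`.
#' @export
feature_block <- function(block_name, x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)), all(is.finite(x)))
  structure(list(block_name = block_name, x = x), class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block '%s': %d samples x %d features\n",
              x$block_name, nrow(x$x), ncol(x$x)))
  invisible(x)
}
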