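# fixtures and independent brute-force oracles used across test files

BASES <- c("A", "C", "G", "T")

random_dna <- function(L) {
  paste0(sample(BASES, L, replace = TRUE), collapse = "")
}

# sequences with an adenine forced at the center (valid window schema)
random_window <- function(L) {
  s <- sample(BASES, L, replace = TRUE)
  s[(L + 1L) %/% 2L] <- "A"
  paste0(s, collapse = "")
}

make_set <- function(sequences, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(sequences))
  fusion6mA:::new_sample_set(ids, sequences, labels,
                             nchar(sequences[1L]))
}

balanced_window_set <- function(n_per_class, L) {
  seqs <- replicate(2L * n_per_class, random_window(L))
  make_set(seqs, rep(c("positive", "negative"), each = n_per_class))
}

write_temp_fasta <- function(ids, seqs, wrap = NULL) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1L, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    }
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}

# character-by-character reference FASTA parser
reference_parse_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(); seqs <- character(); cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ids <- c(ids, sub("\\s.*$", "", substring(ln, 2L)))
      seqs <- c(seqs, ""); cur <- length(seqs)
    } else {
      seqs[cur] <- paste0(seqs[cur], toupper(ln))
    }
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

# position-by-position lookup oracles for the encoders
oracle_binary <- function(seq) {
  map <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
              G = c(0, 0, 1, 0), T = c(0, 0, 0, 1))
  unlist(map[strsplit(seq, "")[[1L]]], use.names = FALSE)
}

oracle_ncp <- function(seq) {
  map <- list(A = c(1, 1, 1), C = c(0, 0, 1),
              G = c(1, 0, 0), T = c(0, 1, 0))
  unlist(map[strsplit(seq, "")[[1L]]], use.names = FALSE)
}

oracle_kmer <- function(seq, k) {
  words <- sort(apply(expand.grid(rep(list(BASES), k)), 1L, paste0,
                      collapse = ""))
  L <- nchar(seq)
  counts <- setNames(numeric(length(words)), sort(words))
  for (s in 1:(L - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (L - k + 1)
}

oracle_enac <- function(seq, w) {
  L <- nchar(seq)
  out <- numeric(0)
  for (s in 1:(L - w + 1)) {
    win <- strsplit(substr(seq, s, s + w - 1), "")[[1L]]
    out <- c(out, vapply(BASES, function(b) sum(win == b) / w, numeric(1)))
  }
  unname(out)
}

# O(n^2) pair-counting AUC: (concordant + ties/2) / (n_pos * n_neg)
oracle_auc <- function(labels01, scores) {
  pos <- scores[labels01 == 1]; neg <- scores[labels01 == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
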