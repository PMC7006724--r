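#' Read a FASTA file of DNA windows
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' sequences, concatenates wrapped lines, and reports malformed records
#' by index.
#'
#' @param path Path to a FASTA file ('>' headers, optionally wrapped
#'   sequence lines).
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L)) {
    bad <- which(widths == 0L)[1L]
    stop("FASTA parse error in '", path, "': record ", bad, " ('",
         ids[bad], "') has an empty sequence", call. = FALSE)
  }
  if (any(!nzchar(ids))) {
    bad <- which(!nzchar(ids))[1L]
    stop("FASTA parse error in '", path, "': record ", bad,
         " has an empty header", call. = FALSE)
  }
  data.frame(id = ids, sequence = toupper(as.character(seqs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x A data.frame with columns `id` and `sequence` (as returned by
#'   [read_fasta()]) or a `sample_set`.
#' @param path Output path.
#' @param label Optional: when `x` is a `sample_set`, write only samples
#'   with this label ("positive" or "negative").
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, label = NULL) {
  if (inherits(x, "sample_set")) {
    keep <- if (is.null(label)) rep(TRUE, nrow(x$samples)) else
      x$samples$label == label
    x <- data.frame(id = x$samples$sample_id[keep],
                    sequence = x$samples$sequence[keep])
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a sample set from vectors
#'
#' Builds a labeled window set directly from in-memory vectors and
#' validates the benchmark schema (uniform odd length, A/C/G/T only,
#' center adenine).
#'
#' @param sample_id Unique sample identifiers.
#' @param sequence DNA window strings, all the same odd length.
#' @param label "positive"/"negative" per sample.
#' @return A `sample_set`.
#' @export
sample_set <- function(sample_id, sequence, label) {
  stopifnot(length(sample_id) == length(sequence),
            length(sequence) == length(label),
            all(label %in% c("positive", "negative")),
            !anyDuplicated(sample_id))
  L <- nchar(sequence[1L])
  if (L %% 2L == 0L) stop("window length must be odd", call. = FALSE)
  problems <- vapply(seq_along(sequence),
                     function(i) validate_window(sample_id[i], sequence[i], L),
                     character(1))
  if (any(!is.na(problems))) {
    stop("schema violation: ", problems[which(!is.na(problems))[1L]],
         call. = FALSE)
  }
  new_sample_set(sample_id, sequence, label, L)
}

new_sample_set <- function(sample_id, sequence, label, window_length) {
  samples <- data.frame(sample_id = sample_id, sequence = sequence,
                        label = label, stringsAsFactors = FALSE)
  structure(
    list(samples = samples,
         window_length = window_length,
         n_positive = sum(label == "positive"),
         n_negative = sum(label == "negative")),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "sample_set: %d samples (%d positive, %d negative), window length %d bp\n",
    nrow(x$samples), x$n_positive, x$n_negative, x$window_length))
  invisible(x)
}

validate_window <- function(id, seq, L) {
  if (nchar(seq) != L) {
    return(sprintf("sample '%s': length %d, expected %d", id, nchar(seq), L))
  }
  if (grepl("[^ACGT]", seq)) {
    return(sprintf("sample '%s': non-ACGT character", id))
  }
  center <- substr(seq, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
  if (center != "A") {
    return(sprintf("sample '%s': center nucleotide '%s', expected 'A'",
                   id, center))
  }
  NA_character_
}

#' Load a positive/negative FASTA pair as a labeled sample set
#'
#' Reads both files, labels samples by source, and validates the
#' methylation-window schema: uniform odd length, A/C/G/T alphabet only,
#' and an adenine at the center position `(L+1)/2` (1-based). In strict
#' mode any violation is an error citing the offending sample; in lenient
#' mode violating records are dropped with a warning reporting how many.
#'
#' @param positive_path FASTA file of methylated (6mA) windows.
#' @param negative_path FASTA file of unmethylated windows.
#' @param strict Reject (TRUE, default) or drop (FALSE) invalid records.
#' @return A `sample_set`.
#' @export
load_benchmark <- function(positive_path, negative_path, strict = TRUE) {
  pos <- read_fasta(positive_path)
  neg <- read_fasta(negative_path)
  ids <- c(pos$id, neg$id)
  seqs <- c(pos$sequence, neg$sequence)
  labels <- rep(c("positive", "negative"), c(nrow(pos), nrow(neg)))

  # window length: the modal length must be odd; all records are checked
  # against it
  lens <- nchar(seqs)
  L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  if (L %% 2L == 0L) {
    stop("window length ", L, " is even; windows must have an odd length ",
         "so that a single center position exists", call. = FALSE)
  }

  problems <- vapply(seq_along(seqs),
                     function(i) validate_window(ids[i], seqs[i], L),
                     character(1))
  bad <- !is.na(problems)
  if (any(bad)) {
    if (strict) {
      stop("benchmark schema violation: ", problems[which(bad)[1L]],
           if (sum(bad) > 1L) sprintf(" (and %d more)", sum(bad) - 1L),
           call. = FALSE)
    }
    warning("dropped ", sum(bad), " record(s) violating the window schema",
            call. = FALSE)
    ids <- ids[!bad]; seqs <- seqs[!bad]; labels <- labels[!bad]
  }
  if (anyDuplicated(ids)) {
    # ids must be unique across the pooled set; disambiguate by source
    ids <- make.unique(ids, sep = "_dup")
  }
  new_sample_set(ids, seqs, labels, L)
}

#' Load a sample set from a TSV table
#'
#' Alternate tabular loader: expects columns `sample_id`, `label`
#' ("positive"/"negative"), and `sequence`, then applies the same schema
#' validation as [load_benchmark()].
#'
#' @param path TSV file path.
#' @param strict Reject (TRUE) or drop (FALSE) invalid records.
#' @return A `sample_set`.
#' @export
load_sample_tsv <- function(path, strict = TRUE) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  req <- c("sample_id", "label", "sequence")
  if (!all(req %in% names(tab))) {
    stop("TSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$label %in% c("positive", "negative"))) {
    stop("label column must contain only 'positive'/'negative'",
         call. = FALSE)
  }
  tmp_pos <- tempfile(fileext = ".fa"); tmp_neg <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_pos, tmp_neg)))
  pos <- tab[tab$label == "positive", ]
  neg <- tab[tab$label == "negative", ]
  write_fasta(data.frame(id = pos$sample_id, sequence = toupper(pos$sequence)), tmp_pos)
  write_fasta(data.frame(id = neg$sample_id, sequence = toupper(neg$sequence)), tmp_neg)
  load_benchmark(tmp_pos, tmp_neg, strict = strict)
}

#' Symmetrically trim windows around the center adenine
#'
#' Replaces each sequence by the substring covering 1-based positions
#' `center - radius .. center + radius`, giving a new window length of
#' `2 * radius + 1`. The center adenine is preserved.
#'
#' @param set A `sample_set`.
#' @param radius Integer, `1 <= radius <= (L - 1) / 2`.
#' @return A trimmed `sample_set`.
#' @export
trim_to_window <- function(set, radius) {
  stopifnot(inherits(set, "sample_set"))
  L <- set$window_length
  max_r <- (L - 1L) %/% 2L
  if (!is.numeric(radius) || length(radius) != 1L || radius != round(radius) ||
      radius < 1L || radius > max_r) {
    stop("radius must be an integer in [1, ", max_r, "], got ", radius,
         call. = FALSE)
  }
  center <- (L + 1L) %/% 2L
  seqs <- substr(set$samples$sequence, center - radius, center + radius)
  new_sample_set(set$samples$sample_id, seqs, set$samples$label,
                 2L * as.integer(radius) + 1L)
}

# integer matrix of nucleotide codes (A=1, C=2, G=3, T=4), one row per sample
seq_to_int_matrix <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[1L])
  chars <- strsplit(sequences, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), DNA_BASES), nrow = n, ncol = L,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("non-ACGT character in sequence ", bad, call. = FALSE)
  }
  m
}
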