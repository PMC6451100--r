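DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T so that RNA-space inputs can be compared in DNA
#' space throughout the pipeline.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
normalize_dna <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

is_valid_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]*$", x)
}

#' Enumerate the full sequence space of a randomized region
#'
#' @param k region length in nt.
#' @return character vector of all `4^k` DNA k-mers in lexicographic order.
#' @export
all_kmers <- function(k) {
  stopifnot(is.numeric(k), k >= 1, k <= 12)
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

# Character matrix (n x L) from equal-length sequences; errors on ragged input.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("sequences must have equal length for positional comparison")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Hamming distances from one sequence to a set of equal-length sequences
#'
#' @param ref single sequence.
#' @param seqs character vector of sequences of the same length as `ref`.
#' @return integer vector of mismatch counts.
#' @export
hamming_to <- function(ref, seqs) {
  if (length(seqs) == 0L) return(integer(0))
  if (any(nchar(seqs) != nchar(ref))) {
    stop("Hamming distance undefined for sequences of unequal length")
  }
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- seq_char_matrix(seqs)
  as.integer(rowSums(m != matrix(r, nrow = nrow(m), ncol = length(r), byrow = TRUE)))
}

#' Construct a deduplicated sequence count table
#'
#' The substrate of all enrichment statistics: a mapping from variable-region
#' sequence to deduplicated molecule count for one library.
#'
#' @param counts named numeric vector (names are sequences, values counts) or a
#'   data.frame with columns `sequence` and `count`.
#' @param label library label.
#' @return object of class `count_table` with elements `counts` (named numeric,
#'   duplicate sequences summed), `label` and `total`.
#' @export
count_table <- function(counts, label = "library") {
  if (is.data.frame(counts)) {
    stopifnot(all(c("sequence", "count") %in% names(counts)))
    counts <- stats::setNames(as.numeric(counts$count), counts$sequence)
  }
  if (length(counts) && is.null(names(counts))) {
    stop("counts must be named by sequence")
  }
  counts <- counts[counts > 0]
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  names(counts) <- normalize_dna(names(counts))
  structure(list(counts = counts, label = label, total = sum(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s': %d distinct sequences, %.0f molecules\n",
              x$label, length(x$counts), x$total))
  invisible(x)
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  data.frame(sequence = names(x$counts), count = as.numeric(x$counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a count table as TSV
#'
#' @param x `count_table`.
#' @param path output file.
#' @export
write_count_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV (columns `sequence`, `count`)
#'
#' @param path input file.
#' @param label library label; defaults to the file name.
#' @return `count_table`.
#' @export
read_count_table <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  count_table(df, label = label)
}

ct_len <- function(x) {
  L <- unique(nchar(names(x$counts)))
  if (length(L) != 1L) {
    stop("count_table holds sequences of mixed length where a single ",
         "variable-region length is required")
  }
  L
}
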