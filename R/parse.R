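#' Read a FASTQ file into a named sequence vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (plain or gzip FASTQ);
#' qualities are not used by any downstream step.
#'
#' @param path FASTQ file.
#' @return named character vector of reads in DNA space.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- normalize_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Decompose raw reads against an oligo design
#'
#' Applies the structural filters of the library architecture: the constant
#' insert must occur at its expected position (within
#' `design$max_constant_mismatch` mismatches), and, when a 5' anchor is
#' declared, the distance between the anchor and the constant insert must
#' equal the design's required gap. Accepted reads are decomposed into UMI,
#' linker-randomized bases, variable region and insert; the 3' adapter is
#' trimmed from the insert end by longest-prefix match.
#'
#' Dispositions are exhaustive and partition the input:
#' `accepted_correct_length`, `rejected_missing_constant`
#' (constant insert not found where expected), `rejected_bad_anchor_gap`
#' (constant insert present but at the wrong distance from the anchor),
#' `rejected_other` (read too short, or anchor absent).
#'
#' @param reads named character vector of reads (DNA or RNA space), a
#'   `DNAStringSet`, or a path to a FASTQ file.
#' @param design an [oligo_design()].
#' @return list with elements `reads` (data.frame: `read_id`, `umi`,
#'   `linker_random`, `variable_region`, `insert`) and `report`
#'   (class `parse_report`: named disposition counts plus `total`).
#' @examples
#' d <- hissa_design("8N")
#' rd <- paste0(strrep("A", 12), "TGTAGC", "CA", "GACGATTG", "AATGCAAGCAAG")
#' parse_reads(c(r1 = rd), d)$reads$variable_region  # "GACGATTG"
#' @export
parse_reads <- function(reads, design) {
  stopifnot(inherits(design, "oligo_design"))
  if (methods::is(reads, "XStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  } else if (is.character(reads) && length(reads) == 1L && !is_valid_dna(normalize_dna(reads)) &&
             file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  seqs <- normalize_dna(unname(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))

  u <- design$umi_length
  a5 <- nchar(design$anchor5)
  lr <- design$linker_random_length
  vl <- design$variable_length
  ci <- design$constant_insert
  cl <- nchar(ci)
  min_len <- u + a5 + design$required_anchor_gap + cl
  n <- length(seqs)
  disp <- rep("accepted_correct_length", n)

  too_short <- nchar(seqs) < min_len
  disp[too_short] <- "rejected_other"

  ok <- !too_short
  if (a5 > 0L) {
    anchor_obs <- substr(seqs, u + 1L, u + a5)
    bad_anchor <- ok & anchor_obs != design$anchor5
    disp[bad_anchor] <- "rejected_other"
    ok <- ok & !bad_anchor
  }

  # constant insert at its expected coordinate (0-based u + a5 + lr + vl)
  cstart <- u + a5 + lr + vl + 1L
  const_obs <- substr(seqs, cstart, cstart + cl - 1L)
  if (design$max_constant_mismatch == 0L) {
    const_ok <- const_obs == ci
  } else {
    const_ok <- ok & hamming_to(ci, ifelse(nchar(const_obs) == cl, const_obs,
                                           strrep("N", cl))) <= design$max_constant_mismatch
  }
  miss <- which(ok & !const_ok)
  if (length(miss)) {
    # distinguish a displaced constant (wrong anchor gap) from an absent one
    found <- regexpr(ci, seqs[miss], fixed = TRUE)
    if (a5 > 0L) {
      anchor_end0 <- u + a5                       # 0-based end of the anchor
      gap_obs <- (as.integer(found) - 1L) - anchor_end0
      displaced <- found > 0L & gap_obs >= 0L
    } else {
      displaced <- rep(FALSE, length(miss))
    }
    disp[miss[displaced]] <- "rejected_bad_anchor_gap"
    disp[miss[!displaced]] <- "rejected_missing_constant"
    ok[miss] <- FALSE
  }

  acc <- which(ok)
  vstart <- u + a5 + lr + 1L
  insert <- substr(seqs[acc], vstart, nchar(seqs[acc]))
  insert <- trim_adapter(insert, design$adapter3)
  parsed <- data.frame(
    read_id = ids[acc],
    umi = substr(seqs[acc], 1L, u),
    linker_random = substr(seqs[acc], u + a5 + 1L, u + a5 + lr),
    variable_region = substr(seqs[acc], vstart, vstart + vl - 1L),
    insert = insert,
    stringsAsFactors = FALSE
  )
  dispositions <- c("accepted_correct_length", "rejected_missing_constant",
                    "rejected_bad_anchor_gap", "rejected_other")
  report <- structure(
    c(as.list(vapply(dispositions, function(d) sum(disp == d), 0L)),
      list(total = n)),
    class = "parse_report")
  list(reads = parsed, report = report)
}

# Remove the 3' adapter from insert ends: the earliest occurrence of the first
# 6 nt of the adapter is taken as the adapter start; a shorter terminal
# fragment is trimmed only if it matches an adapter prefix exactly. Inserts
# without a detectable adapter are returned unchanged.
trim_adapter <- function(inserts, adapter3) {
  if (!nzchar(adapter3) || length(inserts) == 0L) return(inserts)
  probe_len <- min(6L, nchar(adapter3))
  probe <- substr(adapter3, 1L, probe_len)
  pos <- regexpr(probe, inserts, fixed = TRUE)
  hit <- pos > 0L
  inserts[hit] <- substr(inserts[hit], 1L, pos[hit] - 1L)
  # terminal partial adapter (< probe_len nt left at the 3' end)
  for (k in seq_len(probe_len - 1L)) {
    frag <- substr(adapter3, 1L, k)
    tail_match <- !hit & substr(inserts, nchar(inserts) - k + 1L,
                                nchar(inserts)) == frag
    inserts[tail_match] <- substr(inserts[tail_match], 1L,
                                  nchar(inserts[tail_match]) - k)
  }
  inserts
}

#' @export
print.parse_report <- function(x, ...) {
  cat("parse_report:\n")
  for (nm in setdiff(names(x), "total")) {
    cat(sprintf("  %-28s %d (%.1f%%)\n", nm, x[[nm]],
                if (x$total > 0) 100 * x[[nm]] / x$total else 0))
  }
  cat(sprintf("  %-28s %d\n", "total", x$total))
  invisible(x)
}

#' Write a parse report as TSV
#'
#' @param x `parse_report`.
#' @param path output file.
#' @export
write_parse_report <- function(x, path) {
  df <- data.frame(disposition = names(x), count = unlist(x, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
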