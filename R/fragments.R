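#' Build a genomic read set for the fragment pipeline
#'
#' @param chrom,start,end,strand read coordinates (0-based half-open
#'   start/end, as in BED).
#' @param read_id read identifier; multi-mapping reads appear once per locus
#'   under the same id, and mapping multiplicity is derived from id
#'   duplication when not supplied.
#' @param sequence read sequence 5' to 3' of the read (i.e. already
#'   strand-resolved), or `NA`.
#' @param read_count reads represented by the record (collapsed input).
#' @param mapping_multiplicity number of genomic loci the read maps to;
#'   derived from `read_id` duplication when `NULL`.
#' @return `GRanges` with metadata columns `read_id`, `sequence`,
#'   `read_count`, `mapping_multiplicity`.
#' @export
genomic_reads <- function(chrom, start, end, strand, read_id = NULL,
                          sequence = NA_character_, read_count = 1L,
                          mapping_multiplicity = NULL) {
  stopifnot(all(end > start), all(strand %in% c("+", "-")))
  n <- length(chrom)
  if (is.null(read_id)) read_id <- paste0("read", seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),  # BED -> 1-based
    strand = strand)
  S4Vectors::mcols(gr)$read_id <- read_id
  S4Vectors::mcols(gr)$sequence <- normalize_dna(rep_len(sequence, n))
  S4Vectors::mcols(gr)$read_count <- rep_len(as.numeric(read_count), n)
  if (is.null(mapping_multiplicity)) {
    mapping_multiplicity <- as.integer(table(read_id)[read_id])
  }
  S4Vectors::mcols(gr)$mapping_multiplicity <-
    rep_len(as.integer(mapping_multiplicity), n)
  gr
}

#' Read mapped reads or an annotation track from BED
#'
#' BED6 via [rtracklayer::import()]; for reads, the BED name field is taken
#' as the read id (repeated ids mark multi-mappers) and the score field as
#' the read count. Sequences, which BED does not carry, can be joined from a
#' FASTA of read sequences keyed by read id.
#'
#' @param path BED file.
#' @param sequences optional named character vector or `DNAStringSet` of read
#'   sequences keyed by read id.
#' @return `GRanges` (with read metadata columns when `sequences` or
#'   name/score fields are present).
#' @export
read_bed_reads <- function(path, sequences = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) ids <- paste0("read", seq_along(gr))
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(1, length(gr))
  seqs <- rep(NA_character_, length(gr))
  if (!is.null(sequences)) {
    if (methods::is(sequences, "XStringSet")) {
      sequences <- stats::setNames(as.character(sequences), names(sequences))
    }
    seqs <- unname(normalize_dna(sequences[ids]))
  }
  genomic_reads(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)),
                read_id = ids, sequence = seqs, read_count = score)
}

#' Annotation-based filter cascade for fragment reads
#'
#' Reduces a mapped small-RNA read set to candidate single-stranded mRNA
#' fragments by serial elimination, in order: (1) keep reads lying within
#' annotated gene loci; remove reads overlapping annotated (2) miRNA,
#' (3) siRNA, (4) piRNA and (5) repeat-masker intervals; (6) remove
#' multi-mappers; (7) remove staggered reads; (8) remove reads of length
#' exactly `drop_length` nt. Gene-locus containment and small-RNA removal are
#' strand-aware; repeat-masker removal is strand-agnostic. A read is
#' staggered when another read of the same library overlaps it on the
#' opposite strand (a duplex signature).
#'
#' A missing annotation set (`NULL` entry, e.g. piRNA outside ovary
#' libraries) skips its stage with a warning, recorded in the report.
#'
#' @param reads `GRanges` from [genomic_reads()] or [read_bed_reads()].
#' @param annotations named list of `GRanges` with elements `gene_loci`,
#'   `mirna`, `sirna`, `pirna`, `repeatmasker` (any may be `NULL`).
#' @param drop_length read length removed at the final stage (default 21 nt,
#'   the dominant duplex-derived small-RNA length in fly).
#' @param contained_in_genes require full containment within a gene locus at
#'   stage 1 (default); overlap-only when `FALSE`.
#' @return list: `reads` (surviving `GRanges`) and `report` (data.frame:
#'   `stage`, `skipped`, `removed`, `surviving`).
#' @export
filter_cascade <- function(reads, annotations, drop_length = 21L,
                           contained_in_genes = TRUE) {
  stopifnot(methods::is(reads, "GRanges"))
  ann <- function(nm) annotations[[nm]]
  report <- data.frame(stage = character(0), skipped = logical(0),
                       removed = integer(0), surviving = integer(0),
                       stringsAsFactors = FALSE)
  log_stage <- function(stage, skipped, removed, surviving) {
    rbind(report, data.frame(stage = stage, skipped = skipped,
                             removed = removed, surviving = surviving,
                             stringsAsFactors = FALSE))
  }
  keep_overlap <- function(x, subject, invert, type = "any",
                           ignore_strand = FALSE) {
    hit <- IRanges::overlapsAny(x, subject, type = type,
                                ignore.strand = ignore_strand)
    if (invert) x[!hit] else x[hit]
  }

  cur <- reads
  # stage 1: keep genic reads
  if (is.null(ann("gene_loci"))) {
    warning("gene_loci annotation missing; extraction stage skipped")
    report <- log_stage("gene_loci", TRUE, 0L, length(cur))
  } else {
    before <- length(cur)
    cur <- keep_overlap(cur, ann("gene_loci"), invert = FALSE,
                        type = if (contained_in_genes) "within" else "any")
    report <- log_stage("gene_loci", FALSE, before - length(cur), length(cur))
  }
  # stages 2-5: remove annotated small-RNA classes and repeats
  removal_stages <- c(mirna = FALSE, sirna = FALSE, pirna = FALSE,
                      repeatmasker = TRUE)   # value: strand-agnostic?
  for (nm in names(removal_stages)) {
    if (is.null(ann(nm))) {
      warning(nm, " annotation missing; removal stage skipped")
      report <- log_stage(nm, TRUE, 0L, length(cur))
      next
    }
    before <- length(cur)
    cur <- keep_overlap(cur, ann(nm), invert = TRUE,
                        ignore_strand = removal_stages[[nm]])
    report <- log_stage(nm, FALSE, before - length(cur), length(cur))
  }
  # stage 6: multi-mappers
  before <- length(cur)
  cur <- cur[S4Vectors::mcols(cur)$mapping_multiplicity <= 1L]
  report <- log_stage("multimappers", FALSE, before - length(cur),
                      length(cur))
  # stage 7: staggered reads — opposite-strand overlap with any read of the
  # original library (the duplex partner may itself have been filtered out
  # at an earlier stage, so the test runs against the full input set)
  before <- length(cur)
  hits <- GenomicRanges::findOverlaps(cur, reads, ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(cur))[S4Vectors::queryHits(hits)] !=
    as.character(GenomicRanges::strand(reads))[S4Vectors::subjectHits(hits)]
  staggered <- unique(S4Vectors::queryHits(hits)[opp])
  if (length(staggered)) cur <- cur[-staggered]
  report <- log_stage("staggered", FALSE, before - length(cur), length(cur))
  # stage 8: reads of the dropped length
  before <- length(cur)
  cur <- cur[GenomicRanges::width(cur) != drop_length]
  report <- log_stage(paste0("length_", drop_length), FALSE,
                      before - length(cur), length(cur))

  list(reads = cur, report = report)
}

#' Per-frame 3-nt motif counts of fragment reads
#'
#' For each frame f in `frames`, tallies the 3-mer at read positions
#' f..f+2 (1-based, 5' to 3' of the read), weighted by read count, into a
#' zero-filled 64-slot table. Reads too short for a frame are skipped for
#' that frame.
#'
#' @param reads surviving `GRanges` with a `sequence` metadata column, or a
#'   character vector of read sequences.
#' @param frames frame start positions (default 1:3).
#' @param read_count weights; taken from the `read_count` metadata column for
#'   `GRanges` input.
#' @return matrix of 64 motifs x frames (columns named `frame1`, ...), with a
#'   `skipped` attribute counting reads too short per frame. Summing rows
#'   across columns gives the combined-frames table.
#' @export
frame_motif_counts <- function(reads, frames = 1:3, read_count = NULL) {
  if (methods::is(reads, "GRanges")) {
    seqs <- S4Vectors::mcols(reads)$sequence
    if (is.null(read_count)) read_count <- S4Vectors::mcols(reads)$read_count
  } else {
    seqs <- normalize_dna(reads)
  }
  if (is.null(read_count)) read_count <- rep(1, length(seqs))
  if (any(is.na(seqs))) stop("reads lack sequences")
  motifs <- all_kmers(3L)
  out <- matrix(0, nrow = 64L, ncol = length(frames),
                dimnames = list(motifs, paste0("frame", frames)))
  skipped <- stats::setNames(integer(length(frames)),
                             paste0("frame", frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    long_enough <- nchar(seqs) >= f + 2L
    skipped[i] <- sum(!long_enough)
    if (!any(long_enough)) next
    m3 <- substr(seqs[long_enough], f, f + 2L)
    add <- tapply(as.numeric(read_count)[long_enough], m3, sum)
    add <- add[names(add) %in% motifs]
    out[names(add), i] <- add
  }
  attr(out, "skipped") <- skipped
  out
}

#' Motif fold enrichment and exact tests between IP and input
#'
#' For every motif of every frame, fold enrichment is the motif's share of
#' reads in the IP library divided by its share in the input library, and the
#' p-value is the two-sided exact test on the 2x2 table
#' (motif vs other reads, IP vs input). Motifs absent from both libraries
#' get an undefined fold and p = 1.
#'
#' @param ip_counts,input_counts 64 x frames matrices from
#'   [frame_motif_counts()] (or single-column matrices / named vectors for a
#'   combined table).
#' @return data.frame: `frame`, `motif`, `count_ip`, `other_ip`,
#'   `count_input`, `other_input`, `fold_enrichment`, `p_value`, ranked by
#'   descending fold within frame.
#' @export
motif_enrichment <- function(ip_counts, input_counts) {
  if (is.null(dim(ip_counts))) ip_counts <- cbind(combined = ip_counts)
  if (is.null(dim(input_counts))) input_counts <- cbind(combined = input_counts)
  stopifnot(identical(dim(ip_counts), dim(input_counts)))
  out <- lapply(seq_len(ncol(ip_counts)), function(j) {
    a <- as.numeric(ip_counts[, j])
    c_ <- as.numeric(input_counts[, j])
    tot_ip <- sum(a)
    tot_in <- sum(c_)
    if (tot_ip <= 0 || tot_in <= 0) stop("library total is zero")
    b <- tot_ip - a
    d <- tot_in - c_
    fold <- ifelse(a + c_ == 0, NA_real_,
                   ifelse(c_ > 0, (a / tot_ip) / (c_ / tot_in), Inf))
    p <- exact_test_2x2(a, b, c_, d)
    p[a + c_ == 0] <- 1
    df <- data.frame(frame = colnames(ip_counts)[j],
                     motif = rownames(ip_counts),
                     count_ip = a, other_ip = b,
                     count_input = c_, other_input = d,
                     fold_enrichment = fold, p_value = p,
                     row.names = NULL, stringsAsFactors = FALSE)
    sort_key <- df$fold_enrichment
    sort_key[is.na(sort_key)] <- -Inf      # absent from both: last
    df[order(-sort_key, df$motif), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided exact test for 2x2 contingency tables, vectorized
#'
#' Conditional (hypergeometric) exact test: with margins fixed, the p-value
#' sums the probabilities of all tables as or less probable than the observed
#' one (relative tolerance 1e-7, the conventional two-sided rule and the one
#' used by [stats::fisher.test()]). Vectorized over tables and grouped by
#' shared margins so that large collections of tables (e.g. 64 motifs x
#' frames, or whole table spaces in validation) are evaluated efficiently.
#'
#' @param a,b,c,d cell counts of the tables `[a b; c d]` (recycled to a
#'   common length).
#' @return numeric vector of two-sided p-values.
#' @export
exact_test_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  m <- a + b          # row-1 margin
  nn <- c + d         # row-2 margin
  K <- a + c          # column-1 margin
  p <- numeric(n)
  grp <- split(seq_len(n), paste(m, nn, K))
  for (idx in grp) {
    mi <- m[idx[1]]; ni <- nn[idx[1]]; Ki <- K[idx[1]]
    lo <- max(0L, Ki - ni)
    hi <- min(Ki, mi)
    support <- lo:hi
    probs <- stats::dhyper(support, mi, ni, Ki)
    o <- order(probs)
    cum <- cumsum(probs[o])
    obs <- probs[match(a[idx], support)]
    # sum of probabilities <= p_obs * (1 + 1e-7)
    pos <- findInterval(obs * (1 + 1e-7), probs[o])
    p[idx] <- pmin(1, cum[pos])
  }
  p
}
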