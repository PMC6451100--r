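#' Declare a log-linear loading-weight model
#'
#' The selectivity of IP sampling is modelled multiplicatively: every
#' sequence starts at the baseline weight 1 and each matching effect
#' multiplies it. Single effects match one nucleotide at one position; motif
#' effects match a motif at a fixed start (or, with `start = NA`, once per
#' occurrence anywhere); pair effects match a nucleotide pair at two
#' positions. Sequences are then drawn into the IP library with probability
#' proportional to their weight, while the input library is uniform.
#'
#' @param single data.frame with columns `position`, `nucleotide`, `weight`,
#'   or `NULL`.
#' @param motif data.frame with columns `motif`, `start` (`NA` = any
#'   occurrence), `weight`, or `NULL`.
#' @param pair data.frame with columns `pos_i`, `nt_a`, `pos_j`, `nt_b`,
#'   `weight`, or `NULL`.
#' @return object of class `effect_model`.
#' @examples
#' # GAC anchored at the 5' end doubles loading; G raises it 1.3x anywhere
#' m <- effect_model(
#'   single = data.frame(position = 1:8, nucleotide = "G", weight = 1.3),
#'   motif = data.frame(motif = "GAC", start = 1, weight = 2))
#' @export
effect_model <- function(single = NULL, motif = NULL, pair = NULL) {
  chk <- function(df, cols) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df), all(cols %in% names(df)))
    if (any(df$weight <= 0)) stop("effect weights must be > 0")
    df
  }
  structure(list(
    single = chk(single, c("position", "nucleotide", "weight")),
    motif = chk(motif, c("motif", "start", "weight")),
    pair = chk(pair, c("pos_i", "nt_a", "pos_j", "nt_b", "weight"))
  ), class = "effect_model")
}

#' Loading weights of every sequence of the randomized space
#'
#' @param model [effect_model()].
#' @param variable_length randomized-region length L.
#' @return numeric vector of multiplicative weights over [all_kmers()]`(L)`.
#' @export
sequence_weights <- function(model, variable_length) {
  stopifnot(inherits(model, "effect_model"))
  seqs <- all_kmers(variable_length)
  w <- rep(1, length(seqs))
  if (!is.null(model$single)) {
    for (r in seq_len(nrow(model$single))) {
      p <- model$single$position[r]
      hit <- substr(seqs, p, p) == normalize_dna(model$single$nucleotide[r])
      w[hit] <- w[hit] * model$single$weight[r]
    }
  }
  if (!is.null(model$motif)) {
    for (r in seq_len(nrow(model$motif))) {
      mo <- normalize_dna(model$motif$motif[r])
      k <- nchar(mo)
      starts <- if (is.na(model$motif$start[r])) {
        seq_len(variable_length - k + 1L)
      } else {
        as.integer(model$motif$start[r])
      }
      for (s in starts) {
        hit <- substr(seqs, s, s + k - 1L) == mo
        w[hit] <- w[hit] * model$motif$weight[r]
      }
    }
  }
  if (!is.null(model$pair)) {
    for (r in seq_len(nrow(model$pair))) {
      hit <- substr(seqs, model$pair$pos_i[r], model$pair$pos_i[r]) ==
        normalize_dna(model$pair$nt_a[r]) &
        substr(seqs, model$pair$pos_j[r], model$pair$pos_j[r]) ==
        normalize_dna(model$pair$nt_b[r])
      w[hit] <- w[hit] * model$pair$weight[r]
    }
  }
  w
}

#' Draw molecule-level input and IP count tables
#'
#' The molecule-sampling layer of the experiment: input molecules are drawn
#' uniformly over the 4^L randomized sequences, IP molecules with probability
#' proportional to the effect-model weights. This is the ground-truth
#' distribution that the read-level simulator ([simulate_experiment()]) wraps
#' with UMIs, PCR amplification and sequencing errors.
#'
#' @param variable_length randomized-region length.
#' @param model [effect_model()] (empty model = null experiment).
#' @param n_input,n_ip molecules per library.
#' @param seed optional seed (integer) applied via [set.seed()].
#' @return list: `input`, `ip` ([count_table()]s), `weights`.
#' @export
simulate_count_tables <- function(variable_length, model = effect_model(),
                                  n_input, n_ip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- all_kmers(variable_length)
  w <- sequence_weights(model, variable_length)
  draw <- function(n, prob) {
    idx <- sample.int(length(seqs), n, replace = TRUE, prob = prob)
    cnt <- tabulate(idx, nbins = length(seqs))
    count_table(stats::setNames(as.numeric(cnt), seqs)[cnt > 0])
  }
  list(input = draw(n_input, NULL), ip = draw(n_ip, w), weights = w)
}

random_dna <- function(n, len) {
  if (len == 0L) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

draw_amplification <- function(n, spec) {
  if (is.numeric(spec) && length(spec) == 1L) {
    return(rep(as.integer(spec), n))
  }
  if (!is.list(spec) || is.null(spec$type)) {
    stop("amplification spec must be a constant or list(type=, mean=)")
  }
  switch(spec$type,
    geometric = {
      # truncated-at-1 geometric: long right tail of per-molecule PCR yield
      if (is.null(spec$mean) || spec$mean < 1) stop("geometric mean must be >= 1")
      1L + stats::rgeom(n, prob = 1 / spec$mean)
    },
    lognormal = {
      if (is.null(spec$mean) || spec$mean < 1) stop("lognormal mean must be >= 1")
      sdlog <- if (is.null(spec$sdlog)) 1 else spec$sdlog
      pmax(1L, as.integer(round(stats::rlnorm(n, log(spec$mean), sdlog))))
    },
    stop("unknown amplification type: ", spec$type)
  )
}

add_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  stopifnot(length(unique(lens)) == 1L)
  m <- seq_char_matrix(reads)
  mask <- matrix(stats::runif(length(m)) < error_rate, nrow = nrow(m))
  if (any(mask)) {
    # substitute with one of the three other bases, uniformly
    cur <- m[mask]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    m[mask] <- repl
  }
  apply_rows_paste(m)
}

apply_rows_paste <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a full randomized-oligo IP/input experiment
#'
#' Emulates the experiment end to end: a uniform input pool over the 4^L
#' randomized sequences, IP selection proportional to the effect-model
#' weights, per-molecule UMI tagging (uniform random UMIs; collisions are
#' possible and intended), uneven PCR amplification, read assembly following
#' the design layout, and independent per-base substitution errors.
#'
#' @param design [oligo_design()].
#' @param model [effect_model()].
#' @param n_input,n_ip molecules per library.
#' @param amplification per-molecule read-multiplicity distribution: a
#'   constant (e.g. `1`) or `list(type = "geometric", mean = 2)` /
#'   `list(type = "lognormal", mean = 2, sdlog = 1)`.
#' @param error_rate per-base substitution probability (in `[0, 0.25)`).
#' @param seed optional seed applied via [set.seed()].
#' @param fastq_dir if non-`NULL`, gzipped FASTQ files `input.fastq.gz` and
#'   `ip.fastq.gz` are written there.
#' @return list: `input_reads`, `ip_reads` (named character vectors of raw
#'   reads), `truth` (data.frame per molecule: `library`, `molecule_id`,
#'   `variable_region`, `umi`, `linker_random`, `amplification`), `design`,
#'   `model`, and `fastq` (paths, when written).
#' @export
simulate_experiment <- function(design, model = effect_model(),
                                n_input, n_ip,
                                amplification = list(type = "geometric",
                                                     mean = 2),
                                error_rate = 0, seed = NULL,
                                fastq_dir = NULL) {
  stopifnot(inherits(design, "oligo_design"), n_input >= 1, n_ip >= 1,
            error_rate >= 0, error_rate < 0.25)
  if (!is.null(seed)) set.seed(seed)
  L <- design$variable_length
  seqs <- all_kmers(L)
  w <- sequence_weights(model, L)

  one_library <- function(lib, n, prob) {
    idx <- sample.int(length(seqs), n, replace = TRUE, prob = prob)
    vr <- seqs[idx]
    umi <- random_dna(n, design$umi_length)
    linker <- random_dna(n, design$linker_random_length)
    amp <- draw_amplification(n, amplification)
    truth <- data.frame(
      library = lib, molecule_id = sprintf("%s_m%06d", lib, seq_len(n)),
      variable_region = vr, umi = umi, linker_random = linker,
      amplification = amp, stringsAsFactors = FALSE)
    template <- paste0(umi, design$anchor5, linker, vr,
                       design$constant_insert, design$adapter3)
    reads <- rep(template, amp)
    ids <- paste0(rep(truth$molecule_id, amp), "_r",
                  unlist(lapply(amp, seq_len), use.names = FALSE))
    reads <- add_errors(reads, error_rate)
    names(reads) <- ids
    list(truth = truth, reads = reads)
  }
  inp <- one_library("input", n_input, NULL)
  ip <- one_library("ip", n_ip, w)
  out <- list(input_reads = inp$reads, ip_reads = ip$reads,
              truth = rbind(inp$truth, ip$truth),
              design = design, model = model)
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    out$fastq <- c(input = file.path(fastq_dir, "input.fastq.gz"),
                   ip = file.path(fastq_dir, "ip.fastq.gz"))
    write_fastq(inp$reads, out$fastq["input"])
    write_fastq(ip$reads, out$fastq["ip"])
  }
  out
}

#' Write a named sequence vector as gzipped FASTQ
#'
#' @param reads named character vector.
#' @param path output path (".gz" suffix gives gzip).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(x)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(
    xq, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a toy genomic fixture for the fragment pipeline
#'
#' Builds a small single-chromosome read set with controlled annotation
#' overlaps so that every filter stage has known casualties, plus matched IP
#' and input libraries whose surviving reads carry an optional planted
#' frame-anchored motif bias in IP. Expected survivors are recorded by the
#' generator's own construction bookkeeping, independently of the filter
#' implementation.
#'
#' The default emits, per library, `n_survivors` clean genic reads plus one
#' violator per requested category: `outside_gene` (intergenic),
#' `mirna` (in an annotated miRNA), `multimapper` (one read id at two loci)
#' and `length21` (exactly 21 nt) — 10 read ids with 6 expected survivors at
#' the defaults. Categories `sirna`, `pirna`, `repeatmasker` and `staggered`
#' (an antisense partner overlapping a genic read; both members are expected
#' casualties) can be added.
#'
#' @param seed optional seed applied via [set.seed()].
#' @param n_survivors clean reads per library.
#' @param violators character vector of violator categories to include.
#' @param planted_motif 3-nt motif favoured in IP survivor sequences.
#' @param planted_frame frame (1-based read position) at which the motif is
#'   planted.
#' @param motif_weight multiplicative sampling weight of the planted motif at
#'   the planted frame in IP (1 = no bias).
#' @param read_count_mean mean read count per record (Poisson + 1).
#' @return list: `ip`, `input` (`GRanges` read sets), `annotations` (list of
#'   `GRanges`), `expected_survivors` (read ids, identical construction for
#'   both libraries), `planted` (motif, frame, weight).
#' @export
simulate_fragment_fixture <- function(seed = NULL, n_survivors = 6L,
                                      violators = c("outside_gene", "mirna",
                                                    "multimapper",
                                                    "length21"),
                                      planted_motif = "GAC",
                                      planted_frame = 1L,
                                      motif_weight = 1,
                                      read_count_mean = 20) {
  if (!is.null(seed)) set.seed(seed)
  violators <- match.arg(violators,
                         c("outside_gene", "mirna", "sirna", "pirna",
                           "repeatmasker", "multimapper", "staggered",
                           "length21"),
                         several.ok = TRUE)
  ann <- list(
    gene_loci = GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(c(1001, 1001, 50001), c(40000, 40000, 90000)),
      strand = c("+", "-", "+")),
    mirna = GenomicRanges::GRanges("chrS", IRanges::IRanges(2001, 2100), "+"),
    sirna = GenomicRanges::GRanges("chrS", IRanges::IRanges(3001, 3100), "+"),
    pirna = GenomicRanges::GRanges("chrS", IRanges::IRanges(4001, 4100), "+"),
    repeatmasker = GenomicRanges::GRanges("chrS",
                                          IRanges::IRanges(5001, 5100), "+"))

  draw_len <- function(n) sample(c(22L, 23L, 24L, 25L), n, replace = TRUE)
  motif_seq <- function(n, len, bias) {
    motifs <- all_kmers(3L)
    w <- rep(1, 64)
    if (bias != 1) w[motifs == normalize_dna(planted_motif)] <- bias
    lead <- random_dna(n, planted_frame - 1L)
    mid <- motifs[sample.int(64L, n, replace = TRUE, prob = w)]
    tail_len <- len - (planted_frame - 1L) - 3L
    tails <- vapply(tail_len, function(k) random_dna(1L, k), "")
    paste0(lead, mid, tails)
  }

  build_library <- function(lib, bias) {
    starts <- integer(0); lens <- integer(0); strands <- character(0)
    ids <- character(0); cat <- character(0)
    add <- function(id, category, start, len, strand = "+") {
      ids <<- c(ids, id); cat <<- c(cat, category)
      starts <<- c(starts, start); lens <<- c(lens, len)
      strands <<- c(strands, strand)
    }
    surv_start <- 10000L + seq_len(n_survivors) * 100L
    surv_len <- draw_len(n_survivors)
    for (i in seq_len(n_survivors)) {
      add(sprintf("%s_surv%02d", lib, i), "survivor", surv_start[i],
          surv_len[i])
    }
    if ("outside_gene" %in% violators)
      add(paste0(lib, "_outside"), "outside_gene", 95000L, 23L)
    if ("mirna" %in% violators)
      add(paste0(lib, "_mirna"), "mirna", 2020L, 23L)
    if ("sirna" %in% violators)
      add(paste0(lib, "_sirna"), "sirna", 3020L, 23L)
    if ("pirna" %in% violators)
      add(paste0(lib, "_pirna"), "pirna", 4020L, 23L)
    if ("repeatmasker" %in% violators)
      add(paste0(lib, "_rmsk"), "repeatmasker", 5020L, 23L)
    if ("multimapper" %in% violators) {
      add(paste0(lib, "_multi"), "multimapper", 20000L, 23L)
      add(paste0(lib, "_multi"), "multimapper", 30000L, 23L)
    }
    if ("staggered" %in% violators) {
      add(paste0(lib, "_stag_s"), "staggered", 25000L, 23L, "+")
      add(paste0(lib, "_stag_a"), "staggered", 25010L, 23L, "-")
    }
    if ("length21" %in% violators)
      add(paste0(lib, "_len21"), "length21", 35000L, 21L)

    is_surv <- cat == "survivor"
    seqs <- character(length(ids))
    seqs[is_surv] <- motif_seq(sum(is_surv), lens[is_surv], bias)
    seqs[!is_surv] <- vapply(lens[!is_surv],
                             function(k) random_dna(1L, k), "")
    gr <- genomic_reads(rep("chrS", length(ids)), starts, starts + lens,
                        strands, read_id = ids, sequence = seqs,
                        read_count = stats::rpois(length(ids),
                                                  read_count_mean) + 1L)
    S4Vectors::mcols(gr)$category <- cat
    list(reads = gr, survivors = unique(ids[is_surv]))
  }
  ip <- build_library("ip", motif_weight)
  input <- build_library("input", 1)
  list(ip = ip$reads, input = input$reads, annotations = ann,
       expected_survivors = list(ip = ip$survivors,
                                 input = input$survivors),
       planted = list(motif = normalize_dna(planted_motif),
                      frame = planted_frame, weight = motif_weight))
}

#' Write a fragment fixture to BED/FASTA files
#'
#' Reads are written as BED6 (name = read id, score = read count), each
#' annotation set as BED6, and read sequences as FASTA keyed by read id.
#'
#' @param fixture result of [simulate_fragment_fixture()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_fragment_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr_reads <- function(gr, nm) {
    bed <- gr
    S4Vectors::mcols(bed) <- NULL
    S4Vectors::mcols(bed)$name <- S4Vectors::mcols(gr)$read_id
    S4Vectors::mcols(bed)$score <- S4Vectors::mcols(gr)$read_count
    p <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(bed, p, format = "BED")
    fa <- file.path(dir, paste0(nm, ".fa"))
    seqs <- S4Vectors::mcols(gr)$sequence
    keep <- !is.na(seqs) & !duplicated(S4Vectors::mcols(gr)$read_id)
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(seqs[keep]),
                      S4Vectors::mcols(gr)$read_id[keep]), fa)
    c(p, fa)
  }
  paths <- c(paths, wr_reads(fixture$ip, "ip"), wr_reads(fixture$input, "input"))
  for (nm in names(fixture$annotations)) {
    p <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(fixture$annotations[[nm]], p, format = "BED")
    paths <- c(paths, p)
  }
  paths
}
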