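#' Per-sequence enrichment factors (IP vs input)
#'
#' Computes reads-per-million for every variable-region sequence in each
#' library and the enrichment factor `rpm_ip / rpm_input`. Sequences present
#' in both libraries are ranked by descending enrichment factor; sequences
#' absent from one library carry an `NA` factor and rank (no pseudocount is
#' applied unless requested).
#'
#' @param ip,input [count_table()]s from the same design.
#' @param pseudocount count added to every sequence of the union in both
#'   libraries before normalization (default 0, i.e. none).
#' @return data.frame: `sequence`, `rpm_input`, `rpm_ip`,
#'   `enrichment_factor`, `rank` (NA for sequences missing from one library),
#'   sorted by rank with unranked sequences last.
#' @export
per_sequence_enrichment <- function(ip, input, pseudocount = 0) {
  stopifnot(inherits(ip, "count_table"), inherits(input, "count_table"))
  if (ip$total <= 0 || input$total <= 0) {
    stop("empty library: no normalization basis for RPM")
  }
  seqs <- union(names(input$counts), names(ip$counts))
  c_in <- ifelse(seqs %in% names(input$counts),
                 input$counts[seqs], 0) + pseudocount
  c_ip <- ifelse(seqs %in% names(ip$counts), ip$counts[seqs], 0) + pseudocount
  rpm_in <- c_in * 1e6 / sum(c_in)
  rpm_ip <- c_ip * 1e6 / sum(c_ip)
  factor <- ifelse(c_in > 0 & c_ip > 0, rpm_ip / rpm_in, NA_real_)
  rank <- rep(NA_integer_, length(seqs))
  ranked <- which(!is.na(factor))
  rank[ranked[order(-factor[ranked], seqs[ranked])]] <- seq_along(ranked)
  out <- data.frame(sequence = seqs, rpm_input = unname(rpm_in),
                    rpm_ip = unname(rpm_ip),
                    enrichment_factor = unname(factor), rank = rank,
                    stringsAsFactors = FALSE)
  out[order(is.na(out$rank), out$rank), , drop = FALSE]
}

#' Per-position nucleotide composition and enrichment
#'
#' For each position of the randomized region and each nucleotide, the
#' percentage of molecules carrying that nucleotide is computed per library,
#' and the IP/input percentage ratio is log2 transformed. Cells whose input
#' percentage is zero are flagged `NA` rather than propagating infinities.
#'
#' @param ip,input [count_table()]s of equal-length sequences.
#' @return object of class `position_matrix`: list with `percent_input`,
#'   `percent_ip` (L x 4 matrices summing to 100 per row) and `log2_ratio`.
#' @export
per_position_enrichment <- function(ip, input) {
  stopifnot(inherits(ip, "count_table"), inherits(input, "count_table"))
  p_in <- position_percent(input)
  p_ip <- position_percent(ip)
  if (!identical(dim(p_in), dim(p_ip))) {
    stop("libraries have different variable-region lengths")
  }
  ratio <- matrix(NA_real_, nrow(p_in), 4,
                  dimnames = dimnames(p_in))
  ok <- p_in > 0 & p_ip > 0
  ratio[ok] <- log2(p_ip[ok] / p_in[ok])
  structure(list(percent_input = p_in, percent_ip = p_ip, log2_ratio = ratio),
            class = "position_matrix")
}

# L x 4 percentage matrix of nucleotide occupancy, molecule-count weighted.
position_percent <- function(tab) {
  L <- ct_len(tab)
  m <- seq_char_matrix(names(tab$counts))
  w <- as.numeric(tab$counts)
  out <- matrix(0, L, 4, dimnames = list(seq_len(L), DNA_BASES))
  for (b in DNA_BASES) {
    out[, b] <- colSums((m == b) * w)
  }
  100 * out / rowSums(out)
}

#' @export
print.position_matrix <- function(x, ...) {
  cat("position_matrix (log2 IP/input per position x nucleotide):\n")
  print(round(x$log2_ratio, 3))
  invisible(x)
}

#' k-mer motif enrichment over all sequence windows
#'
#' Every length-`k` window of every sequence contributes its molecule count;
#' per-library window frequencies are normalized to sum to 1 over all `4^k`
#' k-mers, and enrichment is the IP/input frequency ratio, ranked descending.
#' This is the randomized-pool k-mer counting scheme of Bind-n-Seq-style
#' analyses, position-independent by construction.
#'
#' @param ip,input [count_table()]s of equal-length sequences.
#' @param k k-mer length (must not exceed the variable-region length).
#' @param positional if `TRUE`, return a long data.frame with a `start`
#'   column giving per-window-start enrichment instead of pooling windows.
#' @return data.frame: `kmer`, `freq_input`, `freq_ip`, `enrichment`, `rank`
#'   (and `start` when `positional`).
#' @export
kmer_enrichment <- function(ip, input, k = 3L, positional = FALSE) {
  stopifnot(inherits(ip, "count_table"), inherits(input, "count_table"))
  L <- ct_len(input)
  if (ct_len(ip) != L) stop("libraries have different variable-region lengths")
  if (k > L) stop("k exceeds the variable-region length")
  kmers <- all_kmers(k)
  starts <- if (positional) seq_len(L - k + 1L) else NA_integer_
  count_windows <- function(tab, start = NULL) {
    seqs <- names(tab$counts)
    w <- as.numeric(tab$counts)
    acc <- stats::setNames(numeric(length(kmers)), kmers)
    rng <- if (is.null(start)) seq_len(L - k + 1L) else start
    for (s in rng) {
      win <- substr(seqs, s, s + k - 1L)
      add <- tapply(w, win, sum)
      acc[names(add)] <- acc[names(add)] + add
    }
    acc
  }
  build <- function(start = NULL) {
    f_in <- count_windows(input, start)
    f_ip <- count_windows(ip, start)
    f_in <- f_in / sum(f_in)
    f_ip <- f_ip / sum(f_ip)
    enr <- ifelse(f_in > 0, f_ip / f_in, NA_real_)
    df <- data.frame(kmer = kmers, freq_input = unname(f_in),
                     freq_ip = unname(f_ip), enrichment = unname(enr),
                     stringsAsFactors = FALSE)
    df$rank <- rank_desc(df$enrichment, df$kmer)
    df[order(is.na(df$rank), df$rank), , drop = FALSE]
  }
  if (!positional) return(build())
  do.call(rbind, lapply(starts, function(s) {
    cbind(start = s, build(s))
  }))
}

rank_desc <- function(values, tie_key) {
  rk <- rep(NA_integer_, length(values))
  ok <- which(!is.na(values))
  rk[ok[order(-values[ok], tie_key[ok])]] <- seq_along(ok)
  rk
}

#' 5'-nucleotide enrichment with optional NAC exclusion
#'
#' For each nucleotide, the log2 ratio of the fraction of molecules starting
#' with that nucleotide in the IP library over the input library. With
#' `exclude_nac = TRUE`, molecules whose second and third positions read "AC"
#' are removed from both libraries first — the re-analysis that asks whether
#' 5' G preference survives outside the GAC motif context.
#'
#' @param ip,input [count_table()]s (sequences of length >= 3 when
#'   `exclude_nac`).
#' @param exclude_nac drop 5'-NAC molecules before computing the enrichment.
#' @return named numeric vector over A, C, G, T (log2; `NA` where a
#'   denominator is zero or the filtered library is empty).
#' @export
five_prime_nucleotide_enrichment <- function(ip, input, exclude_nac = FALSE) {
  stopifnot(inherits(ip, "count_table"), inherits(input, "count_table"))
  filt <- function(tab) {
    cnt <- tab$counts
    if (exclude_nac) {
      cnt <- cnt[substr(names(cnt), 2L, 3L) != "AC"]
    }
    cnt
  }
  frac_by_start <- function(cnt) {
    out <- stats::setNames(numeric(4), DNA_BASES)
    if (length(cnt) == 0L || sum(cnt) == 0) return(out * NA_real_)
    f <- tapply(as.numeric(cnt), substr(names(cnt), 1L, 1L), sum)
    out[names(f)] <- f
    out / sum(out)
  }
  f_in <- frac_by_start(filt(input))
  f_ip <- frac_by_start(filt(ip))
  val <- rep(NA_real_, 4)
  names(val) <- DNA_BASES
  ok <- !is.na(f_in) & !is.na(f_ip) & f_in > 0 & f_ip > 0
  val[ok] <- log2(f_ip[ok] / f_in[ok])
  val
}

#' Summarize an endogenous small-RNA library
#'
#' Sequences are sorted by descending abundance and the smallest prefix whose
#' cumulative share of molecules reaches `top_fraction` is selected. The
#' selected set is scanned for a motif, and a positional nucleotide
#' probability matrix (the numeric content of a sequence logo) is computed
#' over the first `logo_length` positions; sequences shorter than a position
#' simply do not contribute to it. Heterogeneous sequence lengths are allowed.
#'
#' @param library [count_table()] of collapsed endogenous sequences.
#' @param top_fraction cumulative abundance fraction to select (default 0.70).
#' @param motif substring to count among selected sequences (default "GTC").
#' @param logo_length number of positions of the probability matrix.
#' @param by `"abundance"` (cumulative-fraction rule, default) or `"count"`
#'   (top `top_fraction` of distinct sequences).
#' @return list: `selected` (data.frame `sequence`, `count`, `fraction`,
#'   `cumulative`), `motif_count` (selected sequences containing the motif),
#'   `probability_matrix` (`logo_length` x 4, rows summing to 1 where
#'   covered).
#' @export
endogenous_summary <- function(library, top_fraction = 0.70, motif = "GTC",
                               logo_length = 21L,
                               by = c("abundance", "count")) {
  stopifnot(inherits(library, "count_table"))
  by <- match.arg(by)
  if (length(library$counts) == 0L) stop("empty library")
  o <- order(-library$counts, names(library$counts))
  seqs <- names(library$counts)[o]
  cnt <- as.numeric(library$counts)[o]
  frac <- cnt / sum(cnt)
  cum <- cumsum(frac)
  n_sel <- if (by == "abundance") {
    which(cum >= top_fraction)[1L]
  } else {
    max(1L, ceiling(top_fraction * length(seqs)))
  }
  sel <- seq_len(n_sel)
  motif <- normalize_dna(motif)
  motif_count <- sum(grepl(motif, seqs[sel], fixed = TRUE))
  pm <- matrix(NA_real_, logo_length, 4,
               dimnames = list(seq_len(logo_length), DNA_BASES))
  for (p in seq_len(logo_length)) {
    covered <- nchar(seqs[sel]) >= p
    if (!any(covered)) next
    base <- substr(seqs[sel][covered], p, p)
    w <- cnt[sel][covered]
    f <- tapply(w, base, sum)
    row <- stats::setNames(numeric(4), DNA_BASES)
    row[names(f)] <- f
    pm[p, ] <- row / sum(row)
  }
  list(
    selected = data.frame(sequence = seqs[sel], count = cnt[sel],
                          fraction = frac[sel], cumulative = cum[sel],
                          stringsAsFactors = FALSE),
    motif_count = motif_count,
    probability_matrix = pm
  )
}
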