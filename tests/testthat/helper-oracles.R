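# Independent oracles, written as direct transcriptions of the stated rules
# and kept deliberately naive; they never share code with the implementation.

# Iterative error elimination within one group, brute force: repeatedly take
# the highest-count sequence (lexicographically smallest on ties) as the
# representative, delete every sequence within `radius` mismatches of it
# (adding its count to the representative), set the representative aside.
oracle_collapse_group <- function(seqs, counts, radius = 4) {
  survivors <- character(0)
  surv_counts <- numeric(0)
  pool <- data.frame(seq = seqs, count = as.numeric(counts),
                     stringsAsFactors = FALSE)
  naive_hamming <- function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  while (nrow(pool) > 0) {
    best <- pool[pool$count == max(pool$count), , drop = FALSE]
    rep_seq <- sort(best$seq)[1]
    rep_count <- pool$count[pool$seq == rep_seq]
    absorbed <- 0
    drop <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (pool$seq[i] == rep_seq) {
        drop[i] <- TRUE
      } else if (naive_hamming(pool$seq[i], rep_seq) <= radius) {
        absorbed <- absorbed + pool$count[i]
        drop[i] <- TRUE
      }
    }
    survivors <- c(survivors, rep_seq)
    surv_counts <- c(surv_counts, rep_count + absorbed)
    pool <- pool[!drop, , drop = FALSE]
  }
  o <- order(survivors)
  data.frame(seq = survivors[o], count = surv_counts[o],
             stringsAsFactors = FALSE)
}

# Two-sided exact p-value for [a b; c d] by explicit enumeration of the
# conditional distribution using binomial coefficients.
oracle_exact_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  K <- a + c
  lo <- max(0, K - n)
  hi <- min(K, m)
  xs <- lo:hi
  probs <- exp(lchoose(m, xs) + lchoose(n, K - xs) - lchoose(m + n, K))
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random molecule group over a fixed-length alphabet, biased toward clustered
# sequences so that absorption actually happens.
random_group <- function(n_entries, len = 8) {
  n_seeds <- max(1L, rbinom(1, n_entries, 0.3))
  seeds <- replicate(n_seeds, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
  seqs <- character(n_entries)
  for (i in seq_len(n_entries)) {
    s <- sample(seeds, 1)
    sv <- strsplit(s, "")[[1]]
    nmut <- sample(0:6, 1)
    if (nmut > 0) {
      pos <- sample(len, min(nmut, len))
      sv[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    }
    seqs[i] <- paste(sv, collapse = "")
  }
  df <- data.frame(seq = seqs, count = rpois(n_entries, 3) + 1L,
                   stringsAsFactors = FALSE)
  # collapse duplicates: a molecule table holds unique keys
  agg <- aggregate(count ~ seq, df, sum)
  agg[order(agg$seq), , drop = FALSE]
}
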