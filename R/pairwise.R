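#' Enumerate position windows of a randomized region
#'
#' All strictly increasing subsets of `window_size` positions out of
#' `1..length`, in deterministic lexicographic order. Restricting each joint
#' analysis to a window of positions keeps the number of sequence categories
#' per fit manageable (4^window_size) while the union of windows covers every
#' position pair.
#'
#' @param length randomized-region length (8 for the 8-nt design).
#' @param window_size positions per window (default 4).
#' @return list of integer vectors; `choose(length, window_size)` entries
#'   (70 for length 8, size 4).
#' @export
enumerate_windows <- function(length = 8L, window_size = 4L) {
  if (window_size > length) stop("window_size exceeds region length")
  cols <- utils::combn(seq_len(length), window_size)
  lapply(seq_len(ncol(cols)), function(i) as.integer(cols[, i]))
}

# Integer base-4 codes (0..3 per position) and molecule weights for a table.
seq_codes <- function(tab) {
  m <- seq_char_matrix(names(tab$counts))
  codes <- matrix(match(m, DNA_BASES) - 1L, nrow = nrow(m))
  list(codes = codes, w = as.numeric(tab$counts))
}

project_window <- function(codes, w, window) {
  key <- rep(0L, nrow(codes))
  for (p in window) key <- key * 4L + codes[, p]
  acc <- numeric(4L^length(window))
  agg <- rowsum(w, key)
  acc[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  acc
}

#' Project IP and input libraries onto a position window
#'
#' Molecules are projected onto the nucleotides at the window's positions;
#' per-4-mer fractions are computed per library and the response is the log2
#' IP/input fraction ratio for projected k-mers observed in both libraries
#' (others are omitted). The input molecule count is kept as an optional
#' regression weight.
#'
#' @param ip,input [count_table()]s from the same design.
#' @param window strictly increasing integer positions (from
#'   [enumerate_windows()]).
#' @return object of class `window_dataset`: list with `window` and `data`
#'   (data.frame: `kmer`, `n1`..`n4` nucleotide columns, `response`,
#'   `weight`).
#' @export
build_window_dataset <- function(ip, input, window) {
  ci <- seq_codes(input)
  cp <- seq_codes(ip)
  window_dataset_from_codes(ci, cp, window)
}

window_dataset_from_codes <- function(ci, cp, window) {
  window <- as.integer(window)
  stopifnot(all(diff(window) > 0))
  k <- length(window)
  cnt_in <- project_window(ci$codes, ci$w, window)
  cnt_ip <- project_window(cp$codes, cp$w, window)
  keep <- cnt_in > 0 & cnt_ip > 0
  kmers <- all_kmers(k)
  f_in <- cnt_in / sum(cnt_in)
  f_ip <- cnt_ip / sum(cnt_ip)
  df <- data.frame(kmer = kmers[keep], stringsAsFactors = FALSE)
  for (s in seq_len(k)) {
    df[[paste0("n", s)]] <- substr(df$kmer, s, s)
  }
  df$response <- log2(f_ip[keep] / f_in[keep])
  df$weight <- cnt_in[keep]
  structure(list(window = window, data = df), class = "window_dataset")
}

#' Screen and select pairwise nucleotide terms within one window
#'
#' Stage 1 screens each of the `choose(k,2) * 16` (position pair, nucleotide
#' pair) indicators by a single-predictor linear regression of the window
#' responses (two-sided p-value); stage 2 enters the screened terms
#' (`p < alpha`) into a joint linear model subject to bidirectional stepwise
#' selection driven by an information criterion, and reports the coefficients
#' of the retained terms. Indicators that are constant across the window's
#' responses are skipped with a warning.
#'
#' @param dataset a `window_dataset` with at least 3 response entries.
#' @param alpha screening significance level (default 0.1; no multiple-testing
#'   correction is applied at this stage).
#' @param weighted use input molecule counts as regression weights.
#' @param with_main_effects include single (position, nucleotide) indicators
#'   in the joint model alongside the screened pair terms.
#' @param k_ic information-criterion penalty per parameter passed to
#'   [stats::step()] (2 = AIC, `log(n)` = BIC).
#' @return data.frame: `pos_i`, `nt_a`, `pos_j`, `nt_b` (absolute positions),
#'   `p_screen`, `coefficient` (joint-model coefficient of retained terms);
#'   zero rows when nothing survives.
#' @export
screen_and_select <- function(dataset, alpha = 0.1, weighted = FALSE,
                              with_main_effects = FALSE, k_ic = 2) {
  stopifnot(inherits(dataset, "window_dataset"))
  df <- dataset$data
  n <- nrow(df)
  empty <- data.frame(pos_i = integer(0), nt_a = character(0),
                      pos_j = integer(0), nt_b = character(0),
                      p_screen = numeric(0), coefficient = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  k <- length(dataset$window)
  slot_pairs <- utils::combn(k, 2)
  y <- df$response
  w <- if (weighted) df$weight else NULL

  terms <- list()
  X <- list()
  for (pi in seq_len(ncol(slot_pairs))) {
    s <- slot_pairs[1, pi]; t <- slot_pairs[2, pi]
    for (a in DNA_BASES) for (b in DNA_BASES) {
      x <- as.numeric(df[[paste0("n", s)]] == a & df[[paste0("n", t)]] == b)
      nm <- sprintf("x_%d%s_%d%s", dataset$window[s], a,
                    dataset$window[t], b)
      terms[[nm]] <- list(slot_i = s, slot_j = t, nt_a = a, nt_b = b)
      X[[nm]] <- x
    }
  }
  X <- do.call(cbind, X)
  degenerate <- apply(X, 2, function(x) length(unique(x)) < 2L)
  if (any(degenerate)) {
    warning(sum(degenerate), " constant indicator term(s) skipped")
  }
  p <- rep(NA_real_, ncol(X))
  if (is.null(w)) {
    p[!degenerate] <- screen_pvalues(X[, !degenerate, drop = FALSE], y)
  } else {
    for (j in which(!degenerate)) {
      fit <- stats::lm(y ~ X[, j], weights = w)
      p[j] <- summary(fit)$coefficients[2, 4]
    }
  }
  screened <- which(!degenerate & p < alpha)
  if (length(screened) == 0L) return(empty)

  mdf <- as.data.frame(X[, screened, drop = FALSE])
  names(mdf) <- colnames(X)[screened]
  keep_terms <- names(mdf)
  if (with_main_effects) {
    for (s in seq_len(k)) for (a in DNA_BASES[-1]) {
      mdf[[sprintf("m_%d%s", dataset$window[s], a)]] <-
        as.numeric(df[[paste0("n", s)]] == a)
    }
  }
  mdf$.y <- y
  full <- stats::lm(.y ~ ., data = mdf, weights = w)
  sel <- stats::step(full, direction = "both", trace = 0, k = k_ic,
                     scope = list(lower = .y ~ 1))
  coefs <- stats::coef(sel)
  coefs <- coefs[names(coefs) %in% keep_terms & !is.na(coefs)]
  if (length(coefs) == 0L) return(empty)
  nm <- names(coefs)
  info <- terms[nm]
  data.frame(
    pos_i = vapply(info, function(z) dataset$window[z$slot_i], 0L),
    pos_j = vapply(info, function(z) dataset$window[z$slot_j], 0L),
    nt_a = vapply(info, function(z) z$nt_a, ""),
    nt_b = vapply(info, function(z) z$nt_b, ""),
    p_screen = unname(p[match(nm, colnames(X))]),
    coefficient = unname(coefs),
    row.names = NULL, stringsAsFactors = FALSE
  )[, c("pos_i", "nt_a", "pos_j", "nt_b", "p_screen", "coefficient")]
}

# Closed-form two-sided p-values of single binary-indicator OLS fits,
# column-wise over an indicator matrix (algebraically the pooled-variance
# two-sample t-test for each column).
screen_pvalues <- function(X, y) {
  n <- length(y)
  n1 <- colSums(X)
  s1 <- as.numeric(crossprod(X, y))
  q1 <- as.numeric(crossprod(X, y^2))
  n0 <- n - n1
  s0 <- sum(y) - s1
  q0 <- sum(y^2) - q1
  ss <- (q1 - s1^2 / n1) + (q0 - s0^2 / n0)
  sigma2 <- ss / (n - 2)
  se <- sqrt(sigma2 * (1 / n1 + 1 / n0))
  tstat <- (s1 / n1 - s0 / n0) / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[se == 0] <- NA_real_
  p
}

#' Average retained coefficients across windows
#'
#' For every (position, nucleotide) x (position, nucleotide) combination, the
#' mean of its joint-model coefficients over the windows in which the term was
#' retained by selection; windows where it was not retained do not contribute
#' (no zero-filling).
#'
#' @param per_window_selections list of data.frames from
#'   [screen_and_select()], keyed by absolute positions.
#' @return data.frame: `pos_i`, `nt_a`, `pos_j`, `nt_b`, `mean_coefficient`,
#'   `n_windows_retained`, ordered by positions and nucleotides.
#' @export
average_coefficients <- function(per_window_selections) {
  all <- do.call(rbind, per_window_selections)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(pos_i = integer(0), nt_a = character(0),
                      pos_j = integer(0), nt_b = character(0),
                      mean_coefficient = numeric(0),
                      n_windows_retained = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(all$pos_i, all$nt_a, all$pos_j, all$nt_b, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(pos_i = g$pos_i[1], nt_a = g$nt_a[1],
               pos_j = g$pos_j[1], nt_b = g$nt_b[1],
               mean_coefficient = mean(g$coefficient),
               n_windows_retained = nrow(g),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$pos_i, agg$pos_j, agg$nt_a, agg$nt_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Pairwise positional-interaction analysis of an IP/input library pair
#'
#' Runs the full windowed analysis: responses are built for every
#' `choose(L, window_size)` position window, pairwise nucleotide terms are
#' screened (`p < alpha`) and stepwise-selected per window, and coefficients
#' of each retained (position, nucleotide) pair are averaged across windows.
#'
#' @inheritParams screen_and_select
#' @param ip,input [count_table()]s of equal-length sequences.
#' @param window_size positions per window (default 4).
#' @return data.frame as returned by [average_coefficients()].
#' @export
pairwise_interactions <- function(ip, input, window_size = 4L, alpha = 0.1,
                                  weighted = FALSE,
                                  with_main_effects = FALSE, k_ic = 2) {
  L <- ct_len(input)
  if (ct_len(ip) != L) stop("libraries have different variable-region lengths")
  ci <- seq_codes(input)
  cp <- seq_codes(ip)
  windows <- enumerate_windows(L, window_size)
  sels <- lapply(windows, function(wn) {
    ds <- window_dataset_from_codes(ci, cp, wn)
    screen_and_select(ds, alpha = alpha, weighted = weighted,
                      with_main_effects = with_main_effects, k_ic = k_ic)
  })
  average_coefficients(sels)
}

#' Expand averaged interactions to a full (position x nucleotide)^2 matrix
#'
#' @param interactions data.frame from [pairwise_interactions()].
#' @param length randomized-region length.
#' @return 4*length x 4*length numeric matrix (NA where no window retained
#'   the term), rows/columns labelled `pos:nt`.
#' @export
interaction_matrix <- function(interactions, length = 8L) {
  labs <- as.vector(outer(DNA_BASES, seq_len(length),
                          function(b, p) paste0(p, ":", b)))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  if (nrow(interactions)) {
    ri <- paste0(interactions$pos_i, ":", interactions$nt_a)
    rj <- paste0(interactions$pos_j, ":", interactions$nt_b)
    for (r in seq_len(nrow(interactions))) {
      m[ri[r], rj[r]] <- interactions$mean_coefficient[r]
      m[rj[r], ri[r]] <- interactions$mean_coefficient[r]
    }
  }
  m
}
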