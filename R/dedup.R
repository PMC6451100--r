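#' Collapse reads sharing the same UMI and variable region
#'
#' Reads with an identical (UMI, variable-region) combination are assumed to
#' derive from one cDNA molecule through PCR amplification and are collapsed
#' to a single entry carrying the pre-collapse read count.
#'
#' @param parsed data.frame of parsed reads (from [parse_reads()]) with
#'   columns `umi` and `variable_region`; all reads must share one design.
#' @param design_id label propagated to the molecule table.
#' @return list with `table` (class `molecule_table`: data.frame `umi`,
#'   `variable_region`, `read_count`) and `stats` (class `duplication_stats`:
#'   `fraction_amplified` — proportion of reads belonging to entries seen more
#'   than once, `amplification_distribution` — read-count histogram over those
#'   entries, `mean_amplification` — reads per amplified molecule).
#' @export
collapse_exact <- function(parsed, design_id = "design") {
  stopifnot(is.data.frame(parsed),
            all(c("umi", "variable_region") %in% names(parsed)))
  if (nrow(parsed) == 0L) {
    tab <- molecule_table(data.frame(umi = character(0),
                                     variable_region = character(0),
                                     read_count = integer(0)), design_id)
    return(list(table = tab, stats = duplication_stats(integer(0))))
  }
  key <- paste(parsed$umi, parsed$variable_region, sep = "\r")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  tab <- data.frame(
    umi = vapply(parts, `[`, "", 1L),
    variable_region = vapply(parts, `[`, "", 2L),
    read_count = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  list(table = molecule_table(tab, design_id),
       stats = duplication_stats(tab$read_count))
}

#' Construct a molecule table
#'
#' @param df data.frame with columns `umi`, `variable_region`, `read_count`.
#' @param design_id design label.
#' @return `molecule_table` (a data.frame subclass).
#' @export
molecule_table <- function(df, design_id = "design") {
  stopifnot(all(c("umi", "variable_region", "read_count") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("molecule_table", "data.frame"),
            design_id = design_id)
}

duplication_stats <- function(read_counts) {
  amplified <- read_counts[read_counts > 1L]
  structure(list(
    fraction_amplified = if (sum(read_counts) > 0)
      sum(amplified) / sum(read_counts) else NA_real_,
    amplification_distribution = table(amplified),
    mean_amplification = if (length(amplified)) mean(amplified) else NA_real_,
    n_molecules = length(read_counts),
    n_reads = sum(read_counts)
  ), class = "duplication_stats")
}

#' @export
print.duplication_stats <- function(x, ...) {
  cat(sprintf(
    "duplication_stats: %d reads -> %d molecules; %.1f%% of reads amplified (mean %.1f reads/amplified molecule)\n",
    x$n_reads, x$n_molecules, 100 * x$fraction_amplified,
    x$mean_amplification))
  invisible(x)
}

#' Iterative Hamming-distance error elimination
#'
#' Collapses entries that differ only through PCR or sequencing errors.
#' With `group_by = "umi"`, entries are grouped by UMI and the variable-region
#' sequences within each group are collapsed; with `group_by = "insert"`,
#' entries are grouped by variable region and the UMIs are collapsed.
#'
#' Within each group the procedure iterates: (1) the entry with the highest
#' read count is selected as the representative (ties broken by lexicographic
#' order of the collapsed sequence); (2) every other entry within
#' `elimination_radius` mismatches of the representative is eliminated, its
#' read count added to the representative (or dropped when
#' `drop_absorbed = TRUE`); (3) the representative is set aside and the
#' procedure repeats on the remainder until all surviving sequences in the
#' group differ pairwise by more than `elimination_radius`.
#'
#' @param table `molecule_table`.
#' @param group_by `"umi"` or `"insert"`.
#' @param search_radius pre-clustering similarity radius in nt (entries within
#'   this distance are treated as candidate error copies; retained as an
#'   optimization knob, it cannot change the final result because any entry
#'   within the elimination radius of a representative is eliminated
#'   regardless).
#' @param elimination_radius maximum Hamming distance at which an entry is
#'   absorbed by a representative.
#' @param drop_absorbed if `TRUE`, absorbed read counts are discarded instead
#'   of being added to the representative.
#' @return collapsed `molecule_table`; within every group, surviving
#'   sequences differ pairwise by more than `elimination_radius`.
#' @export
error_collapse <- function(table, group_by = c("umi", "insert"),
                           search_radius = 2L, elimination_radius = 4L,
                           drop_absorbed = FALSE) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(table, "molecule_table"))
  if (nrow(table) == 0L) return(table)
  if (group_by == "umi") {
    gkey <- table$umi
    collapse_col <- "variable_region"
  } else {
    gkey <- table$variable_region
    collapse_col <- "umi"
  }
  seqs <- table[[collapse_col]]
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences in the collapsed dimension must have equal length ",
         "(Hamming distance undefined otherwise)")
  }
  idx_by_group <- split(seq_len(nrow(table)), gkey)
  keep_rows <- integer(0)
  new_counts <- numeric(0)
  for (rows in idx_by_group) {
    if (length(rows) == 1L) {
      keep_rows <- c(keep_rows, rows)
      new_counts <- c(new_counts, table$read_count[rows])
      next
    }
    res <- collapse_group(table[[collapse_col]][rows],
                          table$read_count[rows],
                          elimination_radius, drop_absorbed)
    keep_rows <- c(keep_rows, rows[res$keep])
    new_counts <- c(new_counts, res$count)
  }
  out <- table[keep_rows, , drop = FALSE]
  out$read_count <- new_counts
  out <- out[order(out$umi, out$variable_region), , drop = FALSE]
  molecule_table(as.data.frame(out), attr(table, "design_id"))
}

# One group: returns the indices (into the group) of surviving representatives
# and their read counts after absorption.
collapse_group <- function(seqs, counts, radius, drop_absorbed) {
  active <- seq_along(seqs)
  keep <- integer(0)
  kept_counts <- numeric(0)
  counts <- as.numeric(counts)
  while (length(active)) {
    s <- seqs[active]
    cmax <- max(counts[active])
    cand <- active[counts[active] == cmax]
    rep_i <- cand[order(seqs[cand])][1L]          # tie-break: lexicographic
    d <- hamming_to(seqs[rep_i], s)
    absorbed <- active[d <= radius & active != rep_i]
    total <- counts[rep_i] +
      if (drop_absorbed) 0 else sum(counts[absorbed])
    keep <- c(keep, rep_i)
    kept_counts <- c(kept_counts, total)
    active <- setdiff(active, c(rep_i, absorbed))
  }
  o <- order(keep)
  list(keep = keep[o], count = kept_counts[o])
}

#' Reduce a molecule table to deduplicated sequence counts
#'
#' Each distinct molecule (table entry) contributes exactly one count to its
#' variable-region sequence, regardless of how many reads it amplified into.
#'
#' @param table deduplicated `molecule_table`.
#' @param library_label label for the resulting library.
#' @return [count_table()].
#' @export
to_count_table <- function(table, library_label = "library") {
  stopifnot(inherits(table, "molecule_table"))
  if (nrow(table) == 0L) {
    return(count_table(stats::setNames(numeric(0), character(0)),
                       library_label))
  }
  cnt <- table(table$variable_region)
  count_table(stats::setNames(as.numeric(cnt), names(cnt)), library_label)
}

#' Remove endogenous and cross-design contaminant sequences
#'
#' Drops sequences that derive from the endogenous copy of the oligo's
#' constant backbone (within `max_mismatch` mismatches of the corresponding
#' 5' window of a reference) and, when the competing library design is given,
#' sequences whose structure matches an oligo of that other design read under
#' this one (the other design's longer constant tail bleeds its leading bases
#' into this design's variable-region window).
#'
#' @param table `count_table` of variable-region sequences.
#' @param endogenous_refs character vector of endogenous reference sequences
#'   (compared via their first `L` nt, where `L` is the variable-region
#'   length; shorter references are skipped with a warning).
#' @param max_mismatch maximum Hamming distance at which an entry is treated
#'   as an endogenous contaminant.
#' @param other_design `oligo_design` of the competing library, or `NULL`.
#'   Entries are flagged when this design's variable region is longer than
#'   the other's and the entry's trailing bases equal the leading bases of
#'   the other design's constant insert.
#' @return list with `table` (cleaned `count_table`) and `removed`
#'   (data.frame: `sequence`, `count`, `reason`).
#' @export
remove_contaminants <- function(table, endogenous_refs = character(0),
                                max_mismatch = 2L, other_design = NULL) {
  stopifnot(inherits(table, "count_table"))
  seqs <- names(table$counts)
  if (length(seqs) == 0L) {
    return(list(table = table,
                removed = data.frame(sequence = character(0),
                                     count = numeric(0),
                                     reason = character(0))))
  }
  L <- ct_len(table)
  reason <- rep(NA_character_, length(seqs))
  for (ref in normalize_dna(endogenous_refs)) {
    if (nchar(ref) < L) {
      warning("endogenous reference shorter than the variable region; skipped")
      next
    }
    d <- hamming_to(substr(ref, 1L, L), seqs)
    reason[is.na(reason) & d <= max_mismatch] <- "endogenous"
  }
  if (!is.null(other_design)) {
    stopifnot(inherits(other_design, "oligo_design"))
    extra <- L - other_design$variable_length
    if (extra > 0L && nchar(other_design$constant_insert) >= extra) {
      bleed <- substr(other_design$constant_insert, 1L, extra)
      hit <- substr(seqs, L - extra + 1L, L) == bleed
      reason[is.na(reason) & hit] <- "cross_design"
    }
  }
  removed <- !is.na(reason)
  list(
    table = count_table(table$counts[!removed], table$label),
    removed = data.frame(sequence = seqs[removed],
                         count = as.numeric(table$counts[removed]),
                         reason = reason[removed],
                         row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Run the full deduplication pipeline for one library
#'
#' Exact (UMI, insert) collapse followed by the two iterative error-elimination
#' passes: variable regions collapsed within UMI groups, then UMIs collapsed
#' within variable-region groups. Designs without a UMI skip all three steps
#' and feed raw read counts into the count table directly.
#'
#' @param parsed parsed reads data.frame (from [parse_reads()]).
#' @param design `oligo_design`.
#' @param library_label label for the output count table.
#' @param elimination_radius see [error_collapse()].
#' @param error_eliminate if `FALSE`, stop after the exact collapse (no
#'   Hamming error elimination); appropriate for libraries where sequencing
#'   error correction is handled upstream.
#' @return list: `counts` ([count_table()]), `stats`
#'   (`duplication_stats`, `NULL` for UMI-less designs), `molecules`
#'   (`molecule_table`, `NULL` for UMI-less designs).
#' @export
dedup_library <- function(parsed, design, library_label = design$design_id,
                          elimination_radius = 4L, error_eliminate = TRUE) {
  stopifnot(inherits(design, "oligo_design"))
  if (design$umi_length == 0L) {
    cnt <- table(parsed$variable_region)
    return(list(
      counts = count_table(stats::setNames(as.numeric(cnt), names(cnt)),
                           library_label),
      stats = NULL, molecules = NULL))
  }
  ce <- collapse_exact(parsed, design$design_id)
  tab <- ce$table
  if (error_eliminate) {
    tab <- error_collapse(tab, "umi", elimination_radius = elimination_radius)
    tab <- error_collapse(tab, "insert",
                          elimination_radius = elimination_radius)
  }
  list(counts = to_count_table(tab, library_label), stats = ce$stats,
       molecules = tab)
}
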