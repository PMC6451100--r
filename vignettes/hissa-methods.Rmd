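---
title: "Methods: quantifying sequence preferences in ssRNA loading from randomized-oligo IP/input libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sequence preferences in ssRNA loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hissa)
```

## The measurement problem

Argonaute proteins are usually described as sequence-non-specific carriers of
their small-RNA guides, yet single-stranded RNAs are loaded with measurable
sequence selectivity. HISSA (HIgh-throughput Sequencing mediated Specificity
Analysis) measures that selectivity in vitro: a pool of oligos whose 5'
region is randomized (5 or 8 nt) over a constant backbone is incubated in
cell lysate, Argonaute complexes are immunopurified, and both the selected
("IP") and unselected ("input") pools are deep-sequenced. The relative
loading efficiency of a sequence is its abundance ratio between the two
libraries. Everything in this package is a statistic of that ratio, plus the
machinery needed to get trustworthy molecule counts out of raw reads.

The package covers five computational stages:

1. **Structural parsing** (`oligo_design()`, `parse_reads()`) — reads are
   validated against the declared oligo architecture.
2. **Deduplication** (`collapse_exact()`, `error_collapse()`,
   `dedup_library()`) — UMI-based PCR-duplicate collapse with iterative
   Hamming-distance error elimination.
3. **Enrichment statistics** (`per_sequence_enrichment()`,
   `per_position_enrichment()`, `kmer_enrichment()`,
   `five_prime_nucleotide_enrichment()`, `endogenous_summary()`).
4. **Pairwise interaction regression** (`pairwise_interactions()`).
5. **Fragment pipeline** (`filter_cascade()`, `frame_motif_counts()`,
   `motif_enrichment()`) — in vivo follow-up on mapped small-RNA libraries.

A sixth component, the simulator (`simulate_experiment()`,
`simulate_count_tables()`, `simulate_fragment_fixture()`), generates
synthetic experiments with recorded ground truth so that each stage has a
parameter-recovery and calibration test surface.

## Read structure and parsing

A library design declares the layout
`[UMI][anchor5][linker-random][variable][constant insert][adapter3]`,
5' to 3', with 0-based half-open coordinates. The two built-in presets are
the architectures used for fly AGO1/AGO2:

* `hissa_design("5N")` — 5-nt randomized region, no UMI, constant insert
  `TGAAATGCAAGCAAG`.
* `hissa_design("8N")` — 8-nt randomized region, 12-nt UMI, 5' anchor
  `TGTAGC`, 2 linker-randomized bases, constant insert `AATGCAAGCAAG`,
  giving the enforced 10-nt anchor-to-constant gap.

Parsing accepts a read only when the constant insert occurs at its expected
coordinate (exact match by default; `max_constant_mismatch` relaxes it) and,
when an anchor is declared, at the required gap from the anchor. A constant
insert found elsewhere downstream of the anchor is classified as a
wrong-gap rejection; one found nowhere as a missing-constant rejection;
too-short reads and anchor failures fall into a residual class. The four
dispositions always partition the input — this is asserted property-style in
the tests. The UMI and the linker-randomized bases are kept as separate
fields; whether the linker-randomized bases are formally part of the UMI
does not affect any downstream statistic because the two are never compared
across that boundary.

Adapter removal is a longest-prefix match of the 3' adapter at the insert
end (at least 6 nt, or an exact shorter terminal fragment). A read with an
intact insert but no detectable adapter is still accepted: "correct length"
is a property of the insert structure, not of adapter presence. All
comparisons happen in DNA space; U is mapped to T on ingestion. Base
qualities are ignored throughout — the only quality-bearing step in the
original workflow is external QC.

## Deduplication and error elimination

For UMI-carrying designs, reads with identical (UMI, variable-region) pairs
are collapsed to one molecule (`collapse_exact()`), which also yields the
duplication diagnostics (fraction of reads in amplified entries, the
amplification histogram, mean reads per amplified molecule).

PCR and sequencing errors scatter a molecule's reads into near-identical
entries. `error_collapse()` removes them by the iterative representative
rule, within groups: take the highest-count entry as representative
(ties broken lexicographically, so the procedure is deterministic and
seed-free), absorb every entry within Hamming distance 4 of it, set the
representative aside, repeat until the survivors differ pairwise by more
than 4 mismatches. The procedure runs twice: variable regions within UMI
groups, then UMIs within variable-region groups, in that order. The
2-mismatch "similarity" radius that motivates the grouping is retained as a
parameter (`search_radius`) but cannot change the result: any entry within
the elimination radius of a representative is absorbed regardless.

Two choices here were genuinely open:

* **Absorbed counts are added to the representative** rather than discarded,
  so total read counts are conserved and the duplication statistics stay
  meaningful. `drop_absorbed = TRUE` restores literal elimination.
* **"Deduplication" means the exact (UMI, insert) collapse.** The error
  elimination is a distinct error-correction step. The distinction matters
  for the end-to-end identity property: with uniform random 12-nt UMIs,
  collisions are expected (about 3 colliding pairs among 10^4 molecules),
  and a collision whose two inserts happen to lie within Hamming distance 4
  is merged by the elimination pass — so only the exact collapse recovers
  molecule counts exactly on error-free input. The tests assert exact
  recovery for the collapse and a 0.1% band for the full elimination
  pipeline. On error-containing input the elimination passes are what keep
  the molecule count near truth.

Designs without a UMI (the 5-nt libraries) skip all of this; raw read
counts feed the count table directly.

Contaminant removal (`remove_contaminants()`) drops sequences within 2
mismatches of the endogenous copy of the constant backbone's 5' window, and
cross-design bleed-through: an oligo of the shorter-variable design read
under the longer one carries the shorter design's constant-insert prefix at
the end of its variable window, which is a recognizable structural
signature.

## Enrichment statistics

All statistics consume deduplicated `count_table()`s and are invariant to
scaling either library (asserted property-style).

* **Per-sequence** — reads-per-million in each library;
  enrichment factor `rpm_ip / rpm_input`; rank by descending factor. With
  1024 possible 5-mers and typical library depths, nearly every sequence is
  observed, so no pseudocount is applied by default; sequences absent from
  one library are reported with an undefined factor (a `pseudocount`
  argument exists for sparser uses).
* **Per-position** — percentage of molecules carrying each nucleotide at
  each position, per library, and the cellwise log2 IP/input ratio. Cells
  with a zero input percentage are `NA`, never silent infinities.
* **k-mer** — every length-k window of every sequence contributes its
  molecule count; frequencies normalized per library; enrichment is the
  frequency ratio. Pooling windows makes the statistic
  position-independent, which is the right default for a
  position-independent preference (G-richness); `positional = TRUE` exposes
  the per-window-start variant.
* **5'-nucleotide** — log2 ratio of the fraction of molecules starting with
  each base; `exclude_nac = TRUE` first removes molecules whose positions
  2–3 read `AC`, the re-analysis that asks whether a 5'-G preference
  survives outside the GAC context. Fractions (not raw counts) are used;
  the two differ only by the shared totals ratio, which cancels in
  differences between nucleotides.
* **Endogenous library summary** — sequences sorted by abundance; the
  smallest prefix reaching 70% cumulative abundance is selected ("top
  ~70%" read as cumulative share, since sequences are expressed as
  percentages of the total immediately before extraction; `by = "count"`
  selects the top 70% of distinct sequences instead); motif presence is
  substring containment; the positional probability matrix is the numeric
  content of a sequence logo over 21 positions, with shorter sequences
  contributing only to the positions they cover. No plotting dependency:
  matrices are plain numeric output.

## Pairwise positional interactions

Whether a motif acts as a unit, rather than as independent single-position
preferences, is tested by regression on position pairs. The full 8-position
space has 4^8 sequence categories, far too sparse at realistic depths, so
the analysis is windowed: all `choose(8, 4) = 70` 4-position subsets are
analyzed independently; each pair of positions appears in
`choose(6, 2) = 15` windows.

Per window, molecules are projected onto the window's positions, giving up
to 256 projected 4-mers; the **response** is the log2 IP/input fraction
ratio of each 4-mer observed in both libraries. The response choice was
open — it is taken as the same log2 enrichment used by every other statistic
in the package. Weighted least squares by input count is available
(`weighted = TRUE`); the default is unweighted.

Stage 1 screens each of the 6 position-pairs x 16 nucleotide-pairs with a
single-indicator linear regression (p < 0.1, two-sided; no multiple-testing
correction — a deliberate reproduction of the screening convention, not a
statistical endorsement). The implementation uses the closed-form
pooled-variance t, which is algebraically the univariate OLS p-value and
vectorizes across all 96 terms. Stage 2 fits the screened indicators
jointly and runs bidirectional stepwise selection under AIC
(`k_ic = log(n)` gives BIC); main effects can be added with
`with_main_effects = TRUE` but are excluded by default, mirroring the
pair-only formulation. Constant indicators are skipped with a warning.

Coefficients of a retained (position, nucleotide) pair are averaged over
exactly the windows that retained it — no zero-filling — with the retention
count reported alongside. Under a null simulation the per-term screening
pass rate is consistent with the 0.1 level (binomial-band test), and under
a planted 5'-GAC doubling the three pair terms (1G–2A, 2A–3C, 1G–3C) come
back positive.

## The fragment pipeline

For the in vivo question, mapped small-RNA reads (BED) are reduced to
candidate mRNA-fragment (single-strand-derived) reads by serial
elimination, in order: keep reads within annotated gene loci; remove reads
overlapping miRNA, siRNA, piRNA, and repeat-masker annotations; remove
multi-mappers; remove staggered reads; remove 21-nt reads (the dominant
duplex-derived length). The attrition report logs every stage; skipped
stages (e.g. no piRNA set outside ovary data) warn and are recorded.

Interpretation choices, all configurable:

* **Containment vs overlap** — a read "lies within" a gene only if fully
  contained; removal filters trigger on any overlap.
* **Strand** — gene containment and small-RNA removal are strand-aware;
  repeat-masker removal is strand-agnostic (repeat annotations are not
  reliably stranded for this purpose).
* **Staggered reads** — no published definition exists; a read is staggered
  here when any read of the same library overlaps it on the opposite
  strand, the signature of a processed duplex. The test runs against the
  full original library, not the current survivor set: otherwise removing
  one duplex partner at an annotation stage would silently rescue the
  other, and the outcome would depend on stage order.

Surviving reads contribute the 3-mers at positions 1–3, 2–4 and 3–5
(frames 1–3), read-count weighted, into zero-filled 64-slot tables. Fold
enrichment per motif is the IP share divided by the input share, and the
p-value is the two-sided conditional exact test on the 2x2 table (motif vs
rest, IP vs input), summing all tables with probability at most the
observed one (relative tolerance 1e-7 — the same rule as
`stats::fisher.test`). `exact_test_2x2()` implements this via
`stats::dhyper` with margin-grouped vectorization so that entire table
spaces can be evaluated in seconds; the test suite checks it against
`fisher.test` on random tables and against an independent brute-force
binomial-coefficient summation over every table with all margins at most 50
(agreement within 1e-12).

## What the simulator emulates — and what it does not

`simulate_experiment()` reproduces the generative chain of the experiment:

* a **uniform input pool** over the 4^L randomized sequences;
* **IP selection** by a multiplicative (log-linear) weight model
  (`effect_model()`): single-position effects, motif effects at a fixed
  start or per occurrence, and pair effects, all multiplying a baseline of
  1 — so a `GAC`-at-1 weight of 2 makes a GAC-initial sequence exactly
  twice as likely to be sampled as its otherwise-identical counterpart;
* **UMI tagging** with uniform random UMIs — collisions are allowed
  deliberately, so the insert-grouped UMI collapse pass is exercised
  realistically;
* **uneven PCR amplification**, by default geometric truncated at 1
  (mean 2), matching the long right tail of observed duplication levels
  where single molecules can yield hundreds of reads; a log-normal
  alternative is provided;
* **sequencing errors** as independent per-base substitutions.

`simulate_count_tables()` exposes the molecule-sampling layer alone, which
is the right level for calibration and recovery tests of the enrichment
statistics (no read-level nuisance). `simulate_fragment_fixture()` builds a
toy chromosome whose reads violate specific filters by construction; the
expected survivor list comes from the generator's own bookkeeping, never
from the filters under test.

Deliberate non-realism, and hence what passing tests do *not* show about
real data: no indels (all comparisons are fixed-length Hamming), no
quality-score or platform error profile, no sequence-dependent PCR or
ligation bias, no RNA degradation or secondary-structure effects, and an
exactly uniform input pool where real input libraries carry synthesis bias.
Calibration results transfer to real data only to the extent these effects
are second-order.

## Problem sizes, tolerances and numerical choices

The test and acceptance workloads use: 10^4 molecules for the end-to-end
identity (exact recovery asserted), 10^5 molecules per library for null
calibration (mean per-sequence enrichment within [0.97, 1.03]; every
per-position log2 cell within 3 delta-method binomial standard errors of 0)
and for parameter recovery (planted 5'-GAC x2; recovery demanded in at
least 19 of 20 seeded replicates), 200 random groups of up to 100 entries
for dedup-oracle equivalence, and the full space of 2x2 tables with margins
up to 50 (~1.2M tables) for the exact test. These sizes were chosen to make
sampling noise negligible relative to the asserted bands on a single CPU.

Other numerical conventions: ranks break ties lexicographically; zero
denominators yield `NA` flags, never propagated infinities; the
representative rule's determinism means `error_collapse()` is idempotent
(asserted); `set.seed` governs every stochastic path, and identical seeds
give byte-identical simulator output (asserted).

## Known limitations

* The stepwise-selection stage inherits the usual instabilities of stepwise
  regression; the averaging over 15 windows per position pair damps but
  does not remove them. Regularized alternatives are out of scope.
* The pairwise response treats projected 4-mer fractions as independent
  observations; they are weakly negatively correlated through the shared
  multinomial totals. The null-calibration test bounds the practical effect.
* `error_collapse()` is O(n^2) per group in the worst case; groups are
  small in practice (UMI groups at realistic depths), and the acceptance
  workload covers groups up to 100 entries.
* The fragment pipeline consumes already-mapped BED input; mapping itself,
  and genome-scale annotation ingestion, are upstream concerns.
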