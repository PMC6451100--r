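toy_annotations <- function() {
  list(
    gene_loci = GenomicRanges::GRanges(
      "chr2L", IRanges::IRanges(c(101, 101), c(5000, 5000)),
      strand = c("+", "-")),
    mirna = GenomicRanges::GRanges("chr2L", IRanges::IRanges(201, 260), "+"),
    sirna = GenomicRanges::GRanges("chr2L", IRanges::IRanges(401, 460), "+"),
    pirna = GenomicRanges::GRanges("chr2L", IRanges::IRanges(601, 660), "+"),
    repeatmasker = GenomicRanges::GRanges("chr2L",
                                          IRanges::IRanges(801, 860), "-"))
}

test_that("filter_cascade applies the eight stages in order on a hand-built set", {
  ann <- toy_annotations()
  reads <- genomic_reads(
    chrom = rep("chr2L", 10),
    start = c(6000, 210, 410, 610, 810, 1000, 1000, 1200, 1210, 1400),
    end = c(6023, 233, 433, 633, 833, 1023, 1023, 1223, 1233, 1421),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    read_id = c("outside", "in_mir", "in_sir", "in_pir", "in_rmsk",
                "multi", "multi", "stag_s", "stag_a", "len21"),
    sequence = strrep("A", c(23, 23, 23, 23, 23, 23, 23, 23, 23, 21)))
  res <- filter_cascade(reads, ann)
  # hand-derived survivors: nothing — every read violates one filter;
  # staggered pair removes both members
  expect_equal(length(res$reads), 0L)
  expect_equal(res$report$removed,
               c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L))
  # attrition is monotone
  expect_true(all(diff(res$report$surviving) <= 0))
})

test_that("repeat-masker removal is strand-agnostic, small-RNA removal is not", {
  ann <- toy_annotations()
  reads <- genomic_reads(rep("chr2L", 2), c(810, 210), c(833, 233),
                         c("+", "-"),
                         read_id = c("rmsk_opp", "mir_opp"),
                         sequence = strrep("C", c(23, 23)))
  res <- filter_cascade(reads, ann)
  # rmsk annotation is on '-', read on '+': still removed;
  # miRNA annotation on '+', read on '-': kept
  expect_equal(S4Vectors::mcols(res$reads)$read_id, "mir_opp")
})

test_that("missing annotation sets skip their stage with a warning", {
  ann <- toy_annotations()
  ann$pirna <- NULL
  reads <- genomic_reads("chr2L", 610, 633, "+", read_id = "in_pir",
                         sequence = strrep("G", 23))
  expect_warning(res <- filter_cascade(reads, ann), "pirna")
  expect_true(res$report$skipped[res$report$stage == "pirna"])
  expect_equal(length(res$reads), 1L)   # survives: its only violation skipped
})

test_that("a 21-nt read passing all annotation filters dies at the final stage", {
  ann <- toy_annotations()
  reads <- genomic_reads("chr2L", 1500, 1521, "+", sequence = strrep("A", 21))
  res <- filter_cascade(reads, ann)
  expect_equal(length(res$reads), 0L)
  expect_equal(res$report$removed[res$report$stage == "length_21"], 1L)
  kept <- filter_cascade(reads, ann, drop_length = 22L)
  expect_equal(length(kept$reads), 1L)
})

test_that("frame_motif_counts extracts the three 5' frames", {
  fm <- frame_motif_counts("GACGATTG")
  expect_equal(dim(fm), c(64L, 3L))
  expect_equal(fm["GAC", "frame1"], 1)
  expect_equal(fm["ACG", "frame2"], 1)
  expect_equal(fm["CGA", "frame3"], 1)
  # read-count weighting and conservation of surviving totals
  fm2 <- frame_motif_counts(c("GACGATTG", "TTTTTTTT"), read_count = c(3, 2))
  expect_equal(unname(colSums(fm2)), rep(5, 3))
  # combined-frames mode is the sum of per-frame tables
  expect_equal(rowSums(fm2), fm2[, 1] + fm2[, 2] + fm2[, 3])
  # a 4-nt read is skipped for frame 3
  fm3 <- frame_motif_counts("GACG")
  expect_equal(sum(fm3[, "frame3"]), 0)
  expect_equal(attr(fm3, "skipped")[["frame3"]], 1L)
})

test_that("frame motifs follow the read 5' end regardless of strand", {
  # sequences are stored 5'->3' of the read, so strand flips do not alter them
  fx <- simulate_fragment_fixture(seed = 12)
  res <- filter_cascade(fx$ip, fx$annotations)
  fm1 <- frame_motif_counts(res$reads)
  flipped <- res$reads
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(flipped)) == "+", "-", "+")
  fm2 <- frame_motif_counts(flipped)
  expect_equal(fm1, fm2)
})

test_that("motif_enrichment computes fold change and exact p-values", {
  motifs <- all_kmers(3)
  ip <- setNames(rep(0, 64), motifs); input <- ip
  ip["GAC"] <- 10; ip["AAA"] <- 90
  input["GAC"] <- 5; input["AAA"] <- 95
  res <- motif_enrichment(cbind(frame1 = ip), cbind(frame1 = input))
  gac <- res[res$motif == "GAC", ]
  expect_equal(gac$fold_enrichment, 2.0)
  expect_equal(gac$p_value, oracle_exact_p(10, 90, 5, 95))
  expect_equal(gac$p_value, fisher.test(matrix(c(10, 90, 5, 95), 2,
                                               byrow = TRUE))$p.value)
  # identical tables: fold 1, p 1 for observed motifs; absent motifs: NA, 1
  same <- motif_enrichment(cbind(f = ip), cbind(f = ip))
  expect_true(all(same$fold_enrichment[same$count_ip > 0] == 1))
  expect_equal(same$p_value, rep(1, nrow(same)))
  expect_true(all(is.na(same$fold_enrichment[same$count_ip +
                                             same$count_input == 0])))
})

test_that("exact_test_2x2 agrees with fisher.test across random tables", {
  set.seed(424)
  for (i in 1:150) {
    t <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    p1 <- exact_test_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    p2 <- stats::fisher.test(t)$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  # degenerate margins
  expect_equal(exact_test_2x2(0, 0, 0, 0), 1)
  expect_equal(exact_test_2x2(5, 0, 0, 0), 1)
  expect_error(exact_test_2x2(-1, 1, 1, 1), "negative")
})

test_that("the toy fixture's survivors match the generator's bookkeeping", {
  for (s in c(1, 7, 42)) {
    fx <- simulate_fragment_fixture(seed = s)
    for (lib in c("ip", "input")) {
      res <- filter_cascade(fx[[lib]], fx$annotations)
      expect_setequal(S4Vectors::mcols(res$reads)$read_id,
                      fx$expected_survivors[[lib]])
    }
  }
  # full violator set, including staggered pairs and all annotation classes
  fx2 <- simulate_fragment_fixture(seed = 9, violators = c(
    "outside_gene", "mirna", "sirna", "pirna", "repeatmasker",
    "multimapper", "staggered", "length21"))
  res2 <- filter_cascade(fx2$ip, fx2$annotations)
  expect_setequal(S4Vectors::mcols(res2$reads)$read_id,
                  fx2$expected_survivors$ip)
})

test_that("a planted frame-1 motif bias is recovered as fold enrichment", {
  hits <- 0L
  for (s in 1:10) {
    fx <- simulate_fragment_fixture(seed = 2000 + s, n_survivors = 150,
                                    motif_weight = 3)
    ipf <- frame_motif_counts(filter_cascade(fx$ip, fx$annotations)$reads)
    inf <- frame_motif_counts(filter_cascade(fx$input, fx$annotations)$reads)
    res <- motif_enrichment(ipf, inf)
    gac <- res[res$frame == "frame1" & res$motif == "GAC", ]
    if (isTRUE(gac$fold_enrichment > 1)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fixture BED/FASTA round trip preserves reads and counts", {
  fx <- simulate_fragment_fixture(seed = 21)
  dir <- tempfile("fixture")
  paths <- write_fragment_fixture(fx, dir)
  expect_true(all(file.exists(paths)))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "ip.fa"))
  back <- read_bed_reads(file.path(dir, "ip.bed"), sequences = seqs)
  expect_equal(length(back), length(fx$ip))
  df <- function(gr) {
    m <- S4Vectors::mcols(gr)
    out <- data.frame(read_id = m$read_id, start = GenomicRanges::start(gr),
                      read_count = as.numeric(m$read_count),
                      stringsAsFactors = FALSE)
    out[order(out$read_id, out$start), ]
  }
  expect_equal(df(back), df(fx$ip), ignore_attr = TRUE)
  surv <- filter_cascade(back, fx$annotations)
  expect_setequal(S4Vectors::mcols(surv$reads)$read_id,
                  fx$expected_survivors$ip)
})
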