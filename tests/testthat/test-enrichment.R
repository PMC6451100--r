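test_that("per_sequence_enrichment computes RPM ratios and ranks", {
  ip <- count_table(c(AAAAA = 500, GGGGG = 500), "ip")
  input <- count_table(c(AAAAA = 900, GGGGG = 100), "input")
  res <- per_sequence_enrichment(ip, input)
  expect_equal(res$enrichment_factor[res$sequence == "GGGGG"], 5.0)
  expect_equal(res$enrichment_factor[res$sequence == "AAAAA"], 0.5556,
               tolerance = 1e-4)
  expect_equal(res$rank[res$sequence == "GGGGG"], 1L)
  # identity libraries: every factor exactly 1
  same <- per_sequence_enrichment(input, input)
  expect_true(all(same$enrichment_factor == 1))
  # ranks are a permutation over ranked records
  expect_setequal(res$rank[!is.na(res$rank)], seq_len(sum(!is.na(res$rank))))
  expect_error(per_sequence_enrichment(ip, count_table(c(A = 0)[0])), "empty")
})

test_that("sequences absent from one library are reported without a factor", {
  ip <- count_table(c(AAAAA = 10, CCCCC = 5))
  input <- count_table(c(AAAAA = 10, GGGGG = 5))
  res <- per_sequence_enrichment(ip, input)
  expect_true(is.na(res$enrichment_factor[res$sequence == "CCCCC"]))
  expect_true(is.na(res$rank[res$sequence == "GGGGG"]))
  # a pseudocount makes every factor defined
  res2 <- per_sequence_enrichment(ip, input, pseudocount = 1)
  expect_true(all(!is.na(res2$enrichment_factor)))
})

test_that("per_position_enrichment reproduces closed-form log2 ratios", {
  input <- count_table(c(AAAAA = 50, GAAAA = 50))
  ip <- count_table(c(AAAAA = 25, GAAAA = 75))
  pm <- per_position_enrichment(ip, input)
  expect_equal(pm$log2_ratio[1, "A"], -1.0)
  expect_equal(pm$log2_ratio[1, "G"], 0.585, tolerance = 5e-4)
  # identical libraries: all defined cells zero
  z <- per_position_enrichment(input, input)
  expect_true(all(z$log2_ratio[!is.na(z$log2_ratio)] == 0))
  # percentages sum to 100 at every position
  expect_equal(unname(rowSums(pm$percent_ip)), rep(100, 5))
  expect_equal(unname(rowSums(pm$percent_input)), rep(100, 5))
  # zero input percentage flagged NA, not infinite
  pm2 <- per_position_enrichment(count_table(c(CAAAA = 1, AAAAA = 1)),
                                 count_table(c(AAAAA = 2)))
  expect_true(is.na(pm2$log2_ratio[1, "C"]))
  expect_true(all(is.finite(pm2$log2_ratio[!is.na(pm2$log2_ratio)])))
})

test_that("enrichment statistics are invariant to library scaling", {
  set.seed(8)
  seqs <- all_kmers(5)
  c_in <- setNames(rpois(64, 30) + 1, sample(seqs, 64))
  c_ip <- setNames(rpois(64, 30) + 1, names(c_in))
  base_seq <- per_sequence_enrichment(count_table(c_ip), count_table(c_in))
  scaled <- per_sequence_enrichment(count_table(c_ip * 7), count_table(c_in))
  expect_equal(scaled$enrichment_factor, base_seq$enrichment_factor)
  base_pos <- per_position_enrichment(count_table(c_ip), count_table(c_in))
  scaled_pos <- per_position_enrichment(count_table(c_ip * 7),
                                        count_table(c_in * 3))
  expect_equal(scaled_pos$log2_ratio, base_pos$log2_ratio)
})

test_that("kmer_enrichment counts all windows of all sequences", {
  ip <- count_table(c(AAAAA = 500, GGGGG = 500))
  input <- count_table(c(AAAAA = 900, GGGGG = 100))
  res <- kmer_enrichment(ip, input, k = 3)
  expect_equal(nrow(res), 64L)
  expect_equal(sum(res$freq_input), 1)
  expect_equal(sum(res$freq_ip), 1)
  # L=5, k=3: 3 windows per sequence, all AAA here for the A-homopolymer
  expect_equal(res$freq_input[res$kmer == "AAA"], 0.9)
  expect_equal(res$rank[res$kmer == "GGG"], 1L)
  same <- kmer_enrichment(input, input)
  expect_true(all(same$enrichment[!is.na(same$enrichment)] == 1))
  expect_error(kmer_enrichment(ip, input, k = 6), "exceeds")
})

test_that("a planted GGG weight makes GGG the top-ranked 3-mer", {
  m <- effect_model(motif = data.frame(motif = "GGG", start = NA, weight = 4))
  hits <- 0L
  for (s in 1:10) {
    ct <- simulate_count_tables(5, m, 2e4, 2e4, seed = 4000 + s)
    res <- kmer_enrichment(ct$ip, ct$input, 3)
    hits <- hits + (res$kmer[1] == "GGG")
  }
  expect_gte(hits, 9L)
})

test_that("five_prime_nucleotide_enrichment matches hand arithmetic", {
  input <- count_table(c(GAAAA = 25, AAAAA = 25, CAAAA = 25, TAAAA = 25))
  ip <- count_table(c(GAAAA = 40, AAAAA = 20, CAAAA = 20, TAAAA = 20))
  v <- five_prime_nucleotide_enrichment(ip, input)
  expect_equal(unname(v["G"]), 0.678, tolerance = 5e-4)   # log2(1.6)
  expect_equal(unname(v["A"]), log2(0.8))
  z <- five_prime_nucleotide_enrichment(input, input)
  expect_true(all(z == 0))
})

test_that("NAC exclusion removes 5'-NAC molecules before the computation", {
  input <- count_table(c(GACGA = 50, GGGGA = 25, TACGA = 20, TGGGA = 5))
  ip <- count_table(c(GACGA = 70, GGGGA = 20, TACGA = 8, TGGGA = 2))
  with_nac <- five_prime_nucleotide_enrichment(ip, input)
  without <- five_prime_nucleotide_enrichment(ip, input, exclude_nac = TRUE)
  # dropping the strongly-enriched GAC species reduces the G value
  expect_lt(without["G"], with_nac["G"])
  # hand check on the NAC-excluded sub-library
  expect_equal(unname(without["G"]), log2((20 / 22) / (25 / 30)))
  # degenerate: all molecules are NAC
  only_nac <- count_table(c(GACGA = 1, TACGA = 1))
  expect_true(all(is.na(
    five_prime_nucleotide_enrichment(only_nac, only_nac,
                                     exclude_nac = TRUE))))
})

test_that("endogenous_summary selects the smallest top-fraction prefix", {
  lib <- count_table(setNames(c(70, 20, 10), c("TGTCA", "AAAAA", "CCCCC")))
  res <- endogenous_summary(lib, top_fraction = 0.70)
  expect_equal(res$selected$sequence, "TGTCA")
  expect_equal(res$motif_count, 1L)
  # motif presence counts substring containment only
  res2 <- endogenous_summary(count_table(c(TGTCA = 5, AAAAA = 5)),
                             top_fraction = 1)
  expect_equal(res2$motif_count, 1L)
  expect_error(endogenous_summary(count_table(setNames(numeric(0),
                                                       character(0)))),
               "empty")
})

test_that("the probability matrix is an indicator for a homogeneous selection", {
  lib <- count_table(c(GATTACA = 100))
  res <- endogenous_summary(lib, top_fraction = 0.5, logo_length = 7)
  for (p in 1:7) {
    b <- substr("GATTACA", p, p)
    expect_equal(unname(res$probability_matrix[p, b]), 1)
  }
  # heterogeneous lengths: short sequences only cover their own positions
  lib2 <- count_table(c(GG = 1, GGGG = 1))
  res2 <- endogenous_summary(lib2, top_fraction = 1, logo_length = 5)
  expect_equal(unname(res2$probability_matrix[1, "G"]), 1)
  expect_equal(unname(res2$probability_matrix[3, "G"]), 1)  # long seq only
  expect_true(all(is.na(res2$probability_matrix[5, ])))
})

test_that("top-fraction selection by distinct-sequence count is available", {
  lib <- count_table(setNames(c(50, 30, 10, 10), all_kmers(1)[c(3, 1, 2, 4)]))
  res <- endogenous_summary(lib, top_fraction = 0.5, by = "count")
  expect_equal(nrow(res$selected), 2L)
})
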