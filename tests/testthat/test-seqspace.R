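wt33 <- wt_cdr_default()

test_that("hamming counts differing positions and is a metric", {
  expect_identical(hamming("AAA", "AAA"), 0L)
  expect_identical(hamming("AAA", "AAC"), 1L)
  # six listed substitutions against the canonical wild type
  ch <- strsplit(wt33$sequence, "")[[1]]
  pos <- c(2L, 7L, 13L, 20L, 28L, 33L)
  for (p in pos) ch[p] <- setdiff(aa_alphabet(), ch[p])[1]
  expect_identical(hamming(wt33$sequence, paste(ch, collapse = "")), 6L)
  expect_error(hamming("AA", "AAA"), "equal-length")
  # metric axioms on random triples
  set.seed(11)
  for (i in 1:50) {
    s <- replicate(3, paste(sample(aa_alphabet(), 8, TRUE), collapse = ""))
    expect_identical(hamming(s[1], s[2]), hamming(s[2], s[1]))
    expect_gte(hamming(s[1], s[2]) + hamming(s[2], s[3]),
               hamming(s[1], s[3]))
    expect_identical(hamming(s[1], s[1]), 0L)
  }
})

test_that("wildtype and variant types enforce their invariants", {
  expect_equal(wt33$L, 33L)
  expect_error(wildtype("ABZ"), "invalid amino acid 'B' at position 2")
  v <- variant_of(wt33$sequence, wt33)
  expect_identical(nrow(v$mutations), 0L)
  ch <- wt33$chars; ch[5] <- "W"
  v2 <- variant_of(paste(ch, collapse = ""), wt33)
  expect_identical(v2$mutations$pos0, 4L)
  expect_identical(nrow(v2$mutations), hamming(v2$sequence, wt33$sequence))
  expect_error(variant_of("AAA", wt33), "length")
  expect_error(search_constraints(-1), "d_lim")
})

test_that("random_neighbor stays one substitution away and respects d_lim", {
  sc <- search_constraints(2, toy_ab3)
  wt <- wildtype("AAA")
  # brute-force neighborhood on L=2 over {A,B}: from the wild type the only
  # single-substitution neighbors are BA and AB
  sc2 <- search_constraints(2, c("A", "B"))
  wt2 <- wildtype("AA")
  set.seed(5)
  nb <- unique(replicate(200, random_neighbor("AA", wt2, sc2)))
  expect_setequal(nb, c("BA", "AB"))
  # boundary: a sequence at d_lim never proposes distance d_lim + 1
  set.seed(6)
  for (i in 1:300) {
    prop <- random_neighbor("CCA", wt, sc)   # distance 2 = d_lim
    expect_identical(hamming(prop, "CCA"), 1L)
    expect_lte(hamming(prop, "AAA"), 2L)
  }
  expect_error(random_neighbor("CCC", wt, sc), "violates")
})

test_that("random_neighbor is uniform over the enumerated neighborhood", {
  # interior case: neighborhood is all L*(a-1) single mutants
  sc <- search_constraints(3, toy_ab3)
  wt <- wildtype("AAA")
  set.seed(7)
  draws <- vapply(seq_len(1e5), function(i) random_neighbor("AAA", wt, sc),
                  character(1))
  tab <- table(draws)
  expect_identical(length(tab), neighborhood_size("AAA", wt, sc))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # boundary case: only the k mutated positions may move
  x <- "CCA"  # distance 2, d_lim 2
  sc2 <- search_constraints(2, toy_ab3)
  set.seed(8)
  draws2 <- vapply(seq_len(1e5), function(i) random_neighbor(x, wt, sc2),
                   character(1))
  tab2 <- table(draws2)
  expect_identical(length(tab2), neighborhood_size(x, wt, sc2))
  expect_identical(neighborhood_size(x, wt, sc2), 4L)  # 2 positions x 2 letters
  expect_gt(stats::chisq.test(tab2)$p.value, 0.001)
})

test_that("count_search_space matches both conventions", {
  expect_identical(count_search_space(33, 6, 20, "exact-d-positions"),
                   choose(33, 6) * 20^6)
  expect_identical(count_search_space(5, 0, 20, "up-to-d"), 1)
  expect_identical(count_search_space(3, 1, 2, "up-to-d"), 4)
  # brute-force enumeration oracle for small spaces
  for (L in 2:4) for (a in 2:4) for (d in 0:2) {
    space <- enumerate_space(L, LETTERS[seq_len(a)])
    wt <- strrep("A", L)
    n_enum <- sum(vapply(space, function(s)
      sum(strsplit(s, "")[[1]] != strsplit(wt, "")[[1]]) <= d, logical(1)))
    expect_equal(count_search_space(L, d, a, "up-to-d"), n_enum)
  }
})

test_that("diversity, novelty and overlap match brute-force oracles", {
  expect_identical(seq_diversity(c("AAA", "AAA")), 0)
  expect_identical(seq_diversity(c("AAA", "ACC")), 2)
  expect_error(seq_diversity("AAA"), "at least 2")
  expect_identical(seq_novelty(c("AAA"), c("AAA", "CCC")), 0)
  expect_identical(seq_novelty("AAC", "AGG"), 2)
  expect_error(seq_novelty("AAA", character(0)), "non-empty")
  set.seed(12)
  S <- replicate(8, paste(sample(toy_ab3, 5, TRUE), collapse = ""))
  ref <- replicate(4, paste(sample(toy_ab3, 5, TRUE), collapse = ""))
  # double-loop oracles
  dd <- outer(S, S, Vectorize(hamming))
  expect_equal(seq_diversity(S), sum(dd) / (8 * 7))
  expect_lte(seq_diversity(S), max(dd))
  nov <- mean(apply(outer(S, ref, Vectorize(hamming)), 1, min))
  expect_equal(seq_novelty(S, ref), nov)
  expect_identical(seq_overlap(c("A", "C"), c("A", "C")), 1)
  expect_identical(seq_overlap(c("A", "C"), c("G", "T")), 0)
  expect_identical(seq_overlap(c("A", "C", "G", "T"),
                               c("A", "W", "Y", "V")), 0.25)
  expect_error(seq_overlap(character(0), "A"), "non-empty")
})

test_that("disjoint 6-mutation sets sit at the maximum distance 12", {
  ch1 <- wt33$chars; ch2 <- wt33$chars
  for (p in 1:6) ch1[p] <- setdiff(aa_alphabet(), ch1[p])[1]
  for (p in 7:12) ch2[p] <- setdiff(aa_alphabet(), ch2[p])[1]
  a <- paste(ch1, collapse = ""); b <- paste(ch2, collapse = "")
  expect_identical(hamming(a, wt33$sequence), 6L)
  expect_identical(hamming(b, wt33$sequence), 6L)
  expect_identical(hamming(a, b), 12L)
  expect_identical(seq_diversity(c(a, b)), 12)
})

test_that("charge score sums the stated per-residue contributions", {
  expect_identical(charge_score("GGGG"), 0)
  expect_equal(charge_score("RKHDE"), 0.1)
  expect_identical(charge_score(wt33$sequence), 0)
})

test_that("instability index follows the dipeptide-weight formula", {
  W <- instability_weights()
  expect_identical(dim(W), c(20L, 20L))
  expect_false(anyNA(W))
  # frozen reference-implementation values
  expect_equal(instability_index(wt33$sequence), 46.960909, tolerance = 1e-6)
  expect_equal(instability_index("ACDEFGHIKLMNPQRSTVWY"), 84.74,
               tolerance = 1e-6)
  expect_equal(instability_index("WWWWWW"), 8.333333, tolerance = 1e-6)
  # 2-mer: (10/2) * weight of the single dipeptide
  expect_equal(instability_index("GG"), 5 * W["G", "G"])
  # homopolymer of a unit-weight self-dipeptide: 10 * (L-1) / L
  expect_equal(W["W", "W"], 1.0)
  expect_equal(instability_index(strrep("W", 10)), 10 * 9 / 10)
  # direct table-lookup oracle on random 33-mers
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(aa_alphabet(), 33, TRUE), collapse = "")
    ch <- strsplit(s, "")[[1]]
    oracle <- 10 / 33 * sum(W[cbind(ch[-33], ch[-1])])
    expect_equal(instability_index(s), oracle)
  }
  # unknown dipeptide falls back to weight 1 with a warning
  W2 <- W; W2["A", "C"] <- NA
  expect_warning(v <- instability_index("AC", weights = W2), "unknown")
  expect_equal(v, 5)
})

test_that("score tables report mutation count, charge and instability", {
  ch <- wt33$chars; ch[c(1, 9)] <- c("K", "E")
  mut <- paste(ch, collapse = "")
  df <- score_table(c(wt33$sequence, mut), wt33)
  expect_identical(df$n_mutations, c(0L, 2L))
  expect_identical(df$charge[1], 0)
  expect_equal(df$charge[2], 1 - 1)   # one K gained, one E gained
  expect_equal(df$instability[1], instability_index(wt33$sequence))
})

test_that("FASTA round trip preserves sequences and ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(run1_rank1 = wt33$sequence, run1_rank2 = strrep("AC", 16))
  write_fasta_seqs(seqs, tmp)
  back <- read_fasta_seqs(tmp)
  expect_identical(back, c(run1_rank1 = wt33$sequence,
                           run1_rank2 = strrep("AC", 16)))
})
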