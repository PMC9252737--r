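test_that("selection_statistics reports per-round unique fractions", {
  all_same <- round_from_counts(c(AAAA = 100), "r1")
  all_diff <- round_table("r2", dereplicate(rand_dna(100, 8)),
                          total_reads = 100, hq_reads = 100)
  stats <- selection_statistics(selection_series(all_same, all_diff))
  expect_equal(stats$fraction_unique[1], 0.01)
  expect_equal(stats$fraction_unique[2],
               stats$unique_count[2] / 100)
  expect_equal(stats$label, c("r1", "r2"))

  # a round with no high-quality reads yields NA with a warning
  empty <- round_table("r0", dereplicate(character()), total_reads = 5,
                       hq_reads = 0)
  expect_warning(s0 <- selection_statistics(selection_series(empty)),
                 "undefined")
  expect_true(is.na(s0$fraction_unique))
})

test_that("a selection series holds 1..10 rounds", {
  rt <- round_from_counts(c(AA = 1))
  expect_error(selection_series(rep(list(rt), 11)), "between 1 and 10")
  expect_silent(selection_series(rep(list(rt), 10)))
  expect_error(selection_series(list()), "between 1 and 10")
})

test_that("top_sequences returns the head of the ranked table", {
  rt <- round_from_counts(c(A = 5, B = 3))
  expect_equal(top_sequences(rt, 1)$sequence, "A")
  expect_equal(nrow(top_sequences(rt, 10)), 2L) # n beyond unique_count
  # equal counts: lexicographically smaller first
  tie <- round_from_counts(c(TTTT = 4, CCCC = 4))
  expect_equal(top_sequences(tie, 2)$sequence, c("CCCC", "TTTT"))
})

test_that("track_sequences computes fractional abundances per round", {
  r1 <- round_from_counts(c(AAAA = 80, CCCC = 20), "r1")
  r2 <- round_from_counts(c(CCCC = 100), "r2")
  ser <- selection_series(r1, r2)
  tr <- track_sequences(ser, c("CCCC", "GGGG"))
  expect_equal(tr$fraction[tr$sequence == "CCCC"], c(0.2, 1.0))
  expect_equal(tr$fraction[tr$sequence == "GGGG"], c(0, 0)) # absent

  # fractions over the complete entry set sum to 1 in every round
  full <- track_sequences(ser, union(r1$entries$sequence,
                                     r2$entries$sequence))
  sums <- tapply(full$fraction, full$round, sum)
  expect_equal(as.numeric(sums), c(1, 1))

  # wide matrix layout preserves the values
  wide <- track_matrix(tr)
  expect_equal(wide$r1, c(0.2, 0))
  expect_equal(wide$r2, c(1, 0))
})

test_that("match_motif implements IUPAC window matching", {
  expect_true(match_motif("AATGCGGTT", "TGCGG"))
  expect_false(match_motif("TGCGA", "TGCGG"))
  expect_true(match_motif("ACG", "RYN")) # A in R, C in Y, G in N
  expect_equal(match_motif(c("AAA", "GTA", "TTT"), "RY"),
               c(FALSE, TRUE, FALSE))
  # U in a pattern is treated as T
  expect_true(match_motif("ATGCGG", "UGCGG"))
  # a read N matches only the pattern code N
  expect_false(match_motif("ANA", "AGA"))
  expect_false(match_motif("ANA", "ARA"))
  expect_true(match_motif("ANA", "ANA"))
  # pattern longer than sequence cannot match
  expect_false(match_motif("AC", "ACGT"))
  expect_error(match_motif("ACGT", "AXG"), "invalid IUPAC")
  expect_error(match_motif("ACGT", ""), "non-empty")
})

test_that("match_motif agrees with a regular-expression oracle", {
  set.seed(31)
  codes <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  n <- 2000
  seqs <- rand_dna(n, 20, alphabet = c("A", "C", "G", "T", "N"))
  pats <- vapply(seq_len(n), function(i) {
    paste(sample(codes, sample(2:6, 1), replace = TRUE), collapse = "")
  }, character(1))
  got <- vapply(seq_len(n), function(i) match_motif(seqs[i], pats[i]),
                logical(1))
  want <- vapply(seq_len(n), function(i) {
    grepl(motif_regex_oracle(pats[i]), seqs[i])
  }, logical(1))
  expect_equal(got, want)
})

test_that("track_motif extracts matching sequences and their fraction", {
  r1 <- round_from_counts(c(AATGCGGA = 10, CCCCCCCC = 90), "r1")
  r2 <- round_from_counts(c(AATGCGGA = 60, TTGCGGTT = 20,
                            CCCCCCCC = 20), "r2")
  ser <- selection_series(r1, r2)
  mt <- track_motif(ser, "TGCGG")
  expect_equal(mt$track$fraction, c(0.1, 0.8))
  expect_equal(sort(mt$per_round$r2$sequence),
               c("AATGCGGA", "TTGCGGTT"))

  # no matches: empty tables, all-zero track
  none <- track_motif(ser, "AAAAAAAA")
  expect_equal(none$track$fraction, c(0, 0))
  expect_equal(nrow(none$per_round$r1), 0L)

  # pattern N matches every entry
  alln <- track_motif(ser, "N")
  expect_equal(alln$track$fraction, c(1, 1))
})

test_that("hamming counts mismatching positions", {
  expect_equal(hamming("AAAA", "AAAA"), 0L)
  expect_equal(hamming("AAAA", "AATT"), 2L)
  expect_error(hamming("AAA", "AAAA"), "equal-length")

  set.seed(32)
  a <- rand_dna(200, 15)
  b <- rand_dna(200, 15)
  oracle <- mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
  expect_equal(hamming(a, b), oracle)
})
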