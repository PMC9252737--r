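test_that("quality_filter applies the whole-read fraction rule", {
  # 50 bases all at Q30 pass a 98% cutoff
  ok <- tibble::tibble(read_id = "a", sequence = strrep("A", 50),
                       quality = qual_at(30, 50))
  expect_equal(nrow(quality_filter(ok, 98)), 1L)

  # 100 bases with exactly 3 below Q20: 97% high-quality < 98% -> removed
  q <- paste0(qual_at(10, 3), qual_at(30, 97))
  bad <- tibble::tibble(read_id = "b", sequence = strrep("A", 100),
                        quality = q)
  expect_equal(nrow(quality_filter(bad, 98)), 0L)
  # ... but 2 below Q20 (98%) is retained: the rule is >2% fails
  q2 <- paste0(qual_at(10, 2), qual_at(30, 98))
  edge <- tibble::tibble(read_id = "c", sequence = strrep("A", 100),
                         quality = q2)
  expect_equal(nrow(quality_filter(edge, 98)), 1L)

  # cutoff 0 retains anything with at least one base
  expect_equal(nrow(quality_filter(bad, 0)), 1L)

  # zero-length records are skipped with a warning
  zl <- tibble::tibble(read_id = "z", sequence = "", quality = "")
  expect_warning(res <- quality_filter(zl, 98), "zero-length")
  expect_equal(nrow(res), 0L)
})

test_that("quality_filter is monotone in the cutoff and matches brute force", {
  set.seed(21)
  n <- 400
  len <- 60
  recs <- tibble::tibble(
    read_id = sprintf("r%d", 1:n),
    sequence = rand_dna(n, len),
    quality = vapply(1:n, function(i) {
      paste(intToUtf8(sample(33:74, len, replace = TRUE), multiple = TRUE),
            collapse = "")
    }, character(1))
  )
  prev <- recs
  for (cutoff in c(0, 50, 90, 98, 100)) {
    kept <- quality_filter(recs, cutoff, q_threshold = 20)
    # brute-force per-read check
    expected <- vapply(recs$quality, function(q) {
      qs <- utf8ToInt(q) - 33L
      mean(qs >= 20) >= cutoff / 100
    }, logical(1), USE.NAMES = FALSE)
    expect_equal(kept$read_id, recs$read_id[expected])
    # monotone: higher cutoff keeps a subset
    expect_true(all(kept$read_id %in% prev$read_id))
    prev <- kept
  }
})

test_that("dereplicate counts, sorts and ranks unique sequences", {
  out <- dereplicate(c("AC", "AC", "GT"))
  expect_equal(out$sequence, c("AC", "GT"))
  expect_equal(out$reads, c(2L, 1L))
  expect_equal(out$rank, c(1L, 2L))

  expect_equal(nrow(dereplicate(character())), 0L)

  solo <- dereplicate(rep("ACGT", 1000))
  expect_equal(solo$reads, 1000L)

  # ties break lexicographically
  tie <- dereplicate(c("TT", "AA", "GG", "TT", "AA", "GG"))
  expect_equal(tie$sequence, c("AA", "GG", "TT"))
})

test_that("dereplicate equals a naive hash-count oracle on random input", {
  set.seed(22)
  seqs <- sample(rand_dna(300, 8), 20000, replace = TRUE)
  out <- dereplicate(seqs)
  oracle <- sort(tapply(rep(1L, length(seqs)), seqs, sum), decreasing = TRUE)
  expect_equal(sum(out$reads), length(seqs))
  expect_equal(nrow(out), length(oracle))
  expect_setequal(out$sequence, names(oracle))
  expect_equal(out$reads, as.integer(oracle[out$sequence]))
  expect_true(all(diff(out$reads) <= 0))
})

test_that("trim_by_position keeps a 1-based inclusive window", {
  read75 <- paste(rep("ACGTT", 15), collapse = "")
  trimmed <- trim_by_position(read75, 32, 71)
  expect_equal(nchar(trimmed), 40L)
  expect_equal(trimmed, substr(read75, 32, 71))

  expect_equal(trim_by_position("ACGT", 1, 4), "ACGT")
  # too-short reads are rejected, not truncated
  expect_true(is.na(trim_by_position(strrep("A", 30), 32, 71)))
  expect_error(trim_by_position("ACGT", 3, 2))
})

test_that("trim_by_primers recovers inserts between first flank occurrences", {
  expect_equal(trim_by_primers("GGACTTTTCCAA", "GGAC", "CCAA"), "TTTT")
  # adjacent flanks leave a zero-length insert -> dropped
  expect_true(is.na(trim_by_primers("GGACCCAA", "GGAC", "CCAA")))
  # missing either flank -> dropped
  expect_true(is.na(trim_by_primers("TTTTCCAA", "GGAC", "CCAA")))
  expect_true(is.na(trim_by_primers("GGACTTTT", "GGAC", "CCAA")))
  # right flank must begin after the left flank ends
  expect_true(is.na(trim_by_primers("CCAAGGAC", "GGAC", "CCAA")))

  # property: left+insert+right always recovers insert when the insert
  # avoids both flanks
  set.seed(23)
  left <- "GGACT"
  right <- "CCAAG"
  inserts <- rand_dna(200, 12, alphabet = c("A", "T"))
  reads <- paste0(left, inserts, right)
  expect_equal(trim_by_primers(reads, left, right), inserts)

  # mismatch-tolerant mode finds a flank with one error
  noisy <- paste0("GGTCT", "ATATATAT", right)
  expect_true(is.na(trim_by_primers(noisy, left, right)))
  expect_equal(trim_by_primers(noisy, left, right, max_mismatch = 1),
               "ATATATAT")
})

test_that("reverse_complement is a Watson-Crick involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT") # palindromic
  expect_equal(reverse_complement("TGCGG"), "CCGCA")
  expect_equal(reverse_complement("AANC"), "GNTT")
  expect_error(reverse_complement("ACGU"), "outside")

  set.seed(24)
  s <- rand_dna(100, 25, alphabet = c("A", "C", "G", "T", "N"))
  expect_equal(reverse_complement(reverse_complement(s)), s)
  # independent character-table oracle
  expect_equal(reverse_complement(s), rc_oracle(s))
})

test_that("preprocess_round runs the full pipeline in order", {
  # 100 identical perfect-quality reads, no trimming
  fq <- write_fastq_fixture(rep("ACGTACGTAC", 100))
  rt <- preprocess_round(fq, preprocess_config(), label = "r1")
  expect_equal(rt$total_reads, 100L)
  expect_equal(rt$hq_reads, 100L)
  expect_equal(rt$unique_count, 1L)
  expect_equal(sum(rt$entries$reads), rt$hq_reads)

  # reads differing only outside the trim window re-aggregate
  fq2 <- write_fastq_fixture(c("AAACGTTTT", "CCACGTGGG"))
  cfg2 <- preprocess_config(trim_mode = "positions", trim_start = 3,
                            trim_end = 6)
  rt2 <- preprocess_round(fq2, cfg2, label = "r1")
  expect_equal(rt2$unique_count, 1L)
  expect_equal(rt2$entries$reads, 2L)
  expect_equal(rt2$entries$sequence, "ACGT")

  # reads failing the trim are excluded from hq_reads
  fq3 <- write_fastq_fixture(c("AAACGTTTT", "AAA"))
  expect_message(rt3 <- preprocess_round(fq3, cfg2, label = "r1"),
                 "dropped at trimming")
  expect_equal(rt3$total_reads, 2L)
  expect_equal(rt3$hq_reads, 1L)

  # max_reads caps raw records before filtering
  rt4 <- preprocess_round(fq, preprocess_config(), max_reads = 10)
  expect_equal(rt4$total_reads, 10L)
})
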