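test_that("greedy abundance-seeded clustering matches the hand trace", {
  rt <- round_from_counts(c(AAAA = 10, AAAT = 5, GGGG = 8, GGGC = 2))
  cl <- cluster_sequences(rt, k = 2, max_edit_distance = 1)
  expect_equal(cl$clusters$cluster_id, c(0L, 1L))
  expect_equal(cl$clusters$peak, c("AAAA", "GGGG"))
  expect_equal(cl$clusters$total_reads, c(15L, 10L))
  m0 <- cluster_members(cl, 1)
  expect_setequal(m0$sequence, c("AAAA", "AAAT"))
  expect_equal(nrow(cl$unclustered), 0L)
})

test_that("degenerate radii behave as documented", {
  rt <- round_from_counts(c(AAAA = 10, AAAT = 5, AATT = 3))
  # huge radius: everything joins the first seed
  one <- cluster_sequences(rt, k = 3, max_edit_distance = 10)
  expect_equal(nrow(one$clusters), 1L)
  expect_equal(one$clusters$n_members, 3L)
  # radius 0: all singletons
  singles <- cluster_sequences(rt, k = 3, max_edit_distance = 0)
  expect_equal(nrow(singles$clusters), 3L)
  expect_true(all(singles$clusters$n_members == 1L))
})

test_that("clustering invariants hold on random instances", {
  set.seed(51)
  for (trial in 1:3) {
    founders <- rand_dna(4, 20)
    seqs <- unlist(lapply(founders, function(f) {
      # mutant cloud around each founder
      vapply(1:30, function(i) {
        ch <- strsplit(f, "")[[1]]
        nmut <- sample(0:3, 1)
        pos <- sample(20, nmut)
        ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        paste(ch, collapse = "")
      }, character(1))
    }))
    rt <- round_table("r", dereplicate(seqs), length(seqs), length(seqs))
    radius <- 4
    cl <- cluster_sequences(rt, k = 8, max_edit_distance = radius)

    # partition: every sequence in exactly one cluster or unclustered
    all_assigned <- c(cl$members$sequence, cl$unclustered$sequence)
    expect_setequal(all_assigned, rt$entries$sequence)
    expect_equal(length(all_assigned), length(unique(all_assigned)))
    # read-count conservation
    expect_equal(sum(cl$clusters$total_reads) + sum(cl$unclustered$reads),
                 rt$hq_reads)
    # every member within the radius of its peak
    for (i in seq_len(nrow(cl$clusters))) {
      mem <- cl$members[cl$members$cluster_id == cl$clusters$cluster_id[i], ]
      d <- as.integer(utils::adist(cl$clusters$peak[i], mem$sequence))
      expect_true(all(d <= radius))
      # peak is the most abundant member
      expect_true(all(cl$clusters$peak_reads[i] >= mem$reads))
    }
    # cluster 0's peak is the globally most abundant sequence
    expect_equal(cl$clusters$peak[1], rt$entries$sequence[1])
    # mass_rank is a permutation ordering clusters by total reads
    expect_setequal(cl$clusters$mass_rank, seq_len(nrow(cl$clusters)))
    by_mass <- cl$clusters[order(cl$clusters$mass_rank), ]
    expect_true(all(diff(by_mass$total_reads) <= 0))
    # cluster_members(rank = 1) returns the largest-mass cluster
    expect_equal(sum(cluster_members(cl, 1)$reads),
                 max(cl$clusters$total_reads))
  }
})

test_that("clustering is stable under permutation of tied input", {
  set.seed(52)
  seqs <- rep(rand_dna(12, 10), each = 3) # all counts equal
  rt1 <- round_table("a", dereplicate(seqs), length(seqs), length(seqs))
  rt2 <- round_table("a", dereplicate(sample(seqs)), length(seqs),
                     length(seqs))
  cl1 <- cluster_sequences(rt1, k = 5, max_edit_distance = 3)
  cl2 <- cluster_sequences(rt2, k = 5, max_edit_distance = 3)
  expect_equal(cl1$clusters, cl2$clusters)
  expect_equal(cl1$members, cl2$members)
})

test_that("argument validation enforces the documented limits", {
  rt <- round_from_counts(c(AAAA = 1))
  expect_error(cluster_sequences(rt, k = 0), "at least 1")
  expect_error(cluster_sequences(rt, k = 51), "at most 50")
  uneven <- round_table("r", dereplicate(c("AAA", "AAAA")), 2, 2)
  expect_error(cluster_sequences(uneven, k = 1, metric = "hamming"),
               "equal-length")
})

test_that("cluster peaks and membership export respect caps and order", {
  rt <- round_from_counts(c(AAAA = 10, AAAT = 5, GGGG = 8, GGGC = 2))
  cl <- cluster_sequences(rt, k = 2, max_edit_distance = 1)
  pk <- cluster_peaks(cl, 1)
  expect_equal(pk$peak, "AAAA")
  expect_equal(nrow(cluster_peaks(cl, 99)), 2L)
  expect_equal(cluster_peaks(cl, 2),
               tibble::tibble(cluster_id = c(0L, 1L),
                              peak = c("AAAA", "GGGG"),
                              peak_reads = c(10L, 8L)))

  full <- export_clusters(cl, member_cap = 1000)
  expect_equal(nrow(full), 4L)
  capped <- export_clusters(cl, member_cap = 3)
  expect_equal(nrow(capped), 3L)
  # within each cluster reads are non-increasing
  for (id in unique(full$cluster_id)) {
    expect_true(all(diff(full$reads[full$cluster_id == id]) <= 0))
  }
})

test_that("track_cluster_peaks delegates to sequence tracking", {
  r1 <- round_from_counts(c(AAAA = 100), "r1")
  r2 <- round_from_counts(c(AAAA = 60, GGGG = 40), "r2")
  cl <- cluster_sequences(r2, k = 2, max_edit_distance = 0)
  tr <- track_cluster_peaks(selection_series(r1, r2), cl, 2)
  expect_equal(tr$fraction[tr$sequence == "AAAA"], c(1, 0.6))
  expect_equal(tr$fraction[tr$sequence == "GGGG"], c(0, 0.4)) # absent early
})
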