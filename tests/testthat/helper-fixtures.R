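# fixtures are built in code at test time; nothing binary on disk

# write a FASTQ file from parallel vectors, return its path
write_fastq_fixture <- function(sequence, quality = NULL,
                                id = sprintf("read%d", seq_along(sequence)),
                                path = tempfile(fileext = ".fastq")) {
  if (is.null(quality)) quality <- strrep("I", nchar(sequence))
  lines <- as.vector(rbind(paste0("@", id), sequence, "+", quality))
  writeLines(lines, path)
  path
}

rand_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# quality string with Q score q at every base
qual_at <- function(q, len) strrep(intToUtf8(q + 33L), len)

# build a round_table directly from a named count vector
round_from_counts <- function(counts, label = "r1") {
  seqs <- rep(names(counts), times = counts)
  round_table(label, dereplicate(seqs), total_reads = length(seqs),
              hq_reads = length(seqs))
}

# tiny zip archives, base64-encoded: a single-member zip holding a
# FASTQ with reads z1=ACGTACGT, z2=TTGGCCAA (quality all 'I'), and a
# two-member variant of the same records
zip_fixture_single_b64 <- paste0(
  "UEsDBBQAAAAIAE9SOF3V0uHZIAAAADAAAAALAAAAcm91bmQuZmFzdHFzqDLkcnR2",
  "DwFhLm0uTyjgcqgy4goJcXd3dnZ0RBYHAFBLAQIUAxQAAAAIAE9SOF3V0uHZIAAA",
  "ADAAAAALAAAAAAAAAAAAAACAAQAAAAByb3VuZC5mYXN0cVBLBQYAAAAAAQABADkA",
  "AABJAAAAAAA=")
zip_fixture_double_b64 <- paste0(
  "UEsDBBQAAAAIAE9SOF3V0uHZIAAAADAAAAAHAAAAYS5mYXN0cXOoMuRydHYPAWEu",
  "bS5PKOByqDLiCglxd3d2dnREFgcAUEsDBBQAAAAIAE9SOF3V0uHZIAAAADAAAAAH",
  "AAAAYi5mYXN0cXOoMuRydHYPAWEubS5PKOByqDLiCglxd3d2dnREFgcAUEsBAhQD",
  "FAAAAAgAT1I4XdXS4dkgAAAAMAAAAAcAAAAAAAAAAAAAAIABAAAAAGEuZmFzdHFQ",
  "SwECFAMUAAAACABPUjhd1dLh2SAAAAAwAAAABwAAAAAAAAAAAAAAgAFFAAAAYi5m",
  "YXN0cVBLBQYAAAAAAgACAGoAAACKAAAAAAA=")

# one-round series in which every observed sequence has count 1
series_from_observed <- function(observed) {
  counts <- stats::setNames(rep(1L, length(observed)), observed)
  selection_series(round_from_counts(counts, "r1"))
}

# independent oracle: reverse complement by character table + rev
rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# independent oracle: IUPAC pattern -> character-class regular expression
motif_regex_oracle <- function(pattern) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN"
  )
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(chars, function(ch) {
    s <- sets[[ch]]
    if (nchar(s) == 1L) s else paste0("[", s, "]")
  }, character(1)), collapse = "")
}

# independent oracle: all sequences between src and tgt on the Hamming
# hypercube (exhaustive enumeration over the differing positions)
hypercube_between_oracle <- function(src, tgt) {
  s <- strsplit(src, "")[[1]]
  t <- strsplit(tgt, "")[[1]]
  dp <- which(s != t)
  d <- length(dp)
  out <- character(0)
  for (mask in 0:(2^d - 1)) {
    v <- s
    take <- bitwAnd(mask, 2^(seq_len(d) - 1)) > 0
    v[dp[take]] <- t[dp[take]]
    out <- c(out, paste(v, collapse = ""))
  }
  setdiff(out, c(src, tgt))
}
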