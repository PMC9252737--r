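#' Pre-processing configuration
#'
#' Bundles the parameters of the pre-processing pipeline: whole-read
#' quality filtering, trimming to the region of interest, and
#' orientation handling for reverse sequencing runs.
#'
#' @param quality_cutoff Percentage in \[0, 100\]. A read is kept iff at
#'   least this percentage of its bases have Q >= `q_threshold`. The
#'   conventional cutoff of 98 removes reads with more than 2% of bases
#'   below Q20.
#' @param q_threshold Phred score a base must reach to count as
#'   high-quality (default 20, i.e. <= 1% base-calling error).
#' @param trim_mode One of `"none"`, `"positions"`, `"primers"`.
#' @param trim_start,trim_end 1-based inclusive coordinates of the
#'   region of interest (used when `trim_mode = "positions"`). A 40-nt
#'   randomized region occupying read positions 32-71 is selected with
#'   `trim_start = 32, trim_end = 71`.
#' @param fwd_primer,rev_flank Constant sequences flanking the region of
#'   interest (used when `trim_mode = "primers"`); the insert strictly
#'   between their first occurrences is retained.
#' @param primer_max_mismatch Mismatches tolerated when locating each
#'   flank (default 0 = exact).
#' @param orientation `"forward"` or `"reverse"`; reverse-run reads are
#'   batch converted to their reverse complements after trimming.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(quality_cutoff = 98,
                              q_threshold = 20L,
                              trim_mode = c("none", "positions", "primers"),
                              trim_start = NULL,
                              trim_end = NULL,
                              fwd_primer = NULL,
                              rev_flank = NULL,
                              primer_max_mismatch = 0L,
                              orientation = c("forward", "reverse")) {
  trim_mode <- match.arg(trim_mode)
  orientation <- match.arg(orientation)
  stopifnot(quality_cutoff >= 0, quality_cutoff <= 100, q_threshold >= 0)
  if (trim_mode == "positions") {
    stopifnot(is.numeric(trim_start), is.numeric(trim_end),
              trim_start >= 1, trim_start <= trim_end)
  }
  if (trim_mode == "primers") {
    stopifnot(is.character(fwd_primer), nzchar(fwd_primer),
              is.character(rev_flank), nzchar(rev_flank))
  }
  structure(
    list(quality_cutoff = quality_cutoff, q_threshold = as.integer(q_threshold),
         trim_mode = trim_mode, trim_start = trim_start, trim_end = trim_end,
         fwd_primer = fwd_primer, rev_flank = rev_flank,
         primer_max_mismatch = as.integer(primer_max_mismatch),
         orientation = orientation),
    class = "preprocess_config"
  )
}

#' Filter reads by whole-read base-call quality
#'
#' Retains a read iff the fraction of its bases with Q >= `q_threshold`
#' is at least `cutoff`/100. With the conventional `cutoff = 98` this
#' removes reads having more than 2% of their nucleotides below Q20.
#' Order is preserved. Zero-length reads are skipped with a warning.
#'
#' @param records A `seq_records` tibble from [read_fastq()].
#' @param cutoff Percentage in \[0, 100\].
#' @param q_threshold Per-base Phred threshold (default 20).
#' @return The retained subset of `records`, in input order.
#' @export
quality_filter <- function(records, cutoff = 98, q_threshold = 20L) {
  stopifnot(is.data.frame(records), cutoff >= 0, cutoff <= 100)
  if (nrow(records) == 0L) {
    return(records)
  }
  len <- nchar(records$quality)
  empty <- len == 0L
  if (any(empty)) {
    warning(sum(empty), " zero-length record(s) skipped", call. = FALSE)
  }
  frac_hq <- vapply(records$quality, function(q) {
    if (nchar(q) == 0L) return(NA_real_)
    qs <- utf8ToInt(q) - 33L
    mean(qs >= q_threshold)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- !empty & frac_hq >= cutoff / 100
  records[keep, , drop = FALSE]
}

#' Dereplicate sequences into unique sequences with read counts
#'
#' Bins identical sequences and counts how many times each unique
#' sequence was read. The result is sorted by read count (descending),
#' ties broken lexicographically, and ranked 1..U so ranks are
#' reproducible.
#'
#' @param sequences Character vector of nucleotide strings.
#' @return A tibble with columns `rank`, `sequence`, `reads`; the sum of
#'   `reads` equals `length(sequences)`.
#' @examples
#' dereplicate(c("AC", "AC", "GT"))
#' @export
dereplicate <- function(sequences) {
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L) {
    return(tibble::tibble(rank = integer(), sequence = character(),
                          reads = integer()))
  }
  counts <- table(sequences)
  out <- tibble::tibble(sequence = names(counts),
                        reads = as.integer(counts))
  # C-locale ordering for reproducible lexicographic tie-breaks
  ord <- order(-out$reads, rank_c_locale(out$sequence))
  out <- out[ord, ]
  tibble::tibble(rank = seq_len(nrow(out)), sequence = out$sequence,
                 reads = out$reads)
}

rank_c_locale <- function(x) {
  withr::with_collate("C", rank(x, ties.method = "first"))
}

#' Trim reads to a fixed coordinate window
#'
#' Extracts positions `start..end` (1-based, inclusive) from each
#' sequence, e.g. `trim_by_position(x, 32, 71)` recovers a 40-nt
#' randomized region occupying read positions 32-71. Reads shorter than
#' `end` cannot supply the full region and are rejected (`NA`), not
#' truncated.
#'
#' @param sequence Character vector of reads.
#' @param start,end 1-based inclusive window, `start <= end`.
#' @return Character vector of trimmed regions; `NA` where the read was
#'   too short.
#' @export
trim_by_position <- function(sequence, start, end) {
  stopifnot(is.numeric(start), is.numeric(end), start >= 1, start <= end)
  out <- ifelse(nchar(sequence) >= end,
                substr(sequence, start, end), NA_character_)
  as.character(out)
}

#' Trim reads to the insert between two flanking constant sequences
#'
#' Returns the substring strictly between the first occurrence of
#' `left_flank` and the first occurrence of `right_flank` that begins
#' after the left flank ends. Reads lacking either flank in that order,
#' or with a zero-length insert (adjacent flanks), are rejected (`NA`).
#'
#' @param sequence Character vector of reads.
#' @param left_flank,right_flank Non-empty uppercase DNA strings
#'   (constant primer/adapter regions).
#' @param max_mismatch Mismatches tolerated per flank (default 0 =
#'   exact matching).
#' @return Character vector of inserts; `NA` where the read was dropped.
#' @export
trim_by_primers <- function(sequence, left_flank, right_flank,
                            max_mismatch = 0L) {
  stopifnot(is.character(left_flank), nzchar(left_flank),
            is.character(right_flank), nzchar(right_flank))
  n <- length(sequence)
  if (n == 0L) return(character())
  if (max_mismatch == 0L) {
    left_at <- as.integer(regexpr(left_flank, sequence, fixed = TRUE))
    ins_start <- left_at + nchar(left_flank)
    tail_str <- ifelse(left_at > 0L, substr(sequence, ins_start, nchar(sequence)),
                       NA_character_)
    right_rel <- as.integer(regexpr(right_flank, tail_str, fixed = TRUE))
    ins_len <- right_rel - 1L
    out <- ifelse(left_at > 0L & !is.na(right_rel) & right_rel > 0L & ins_len > 0L,
                  substr(tail_str, 1L, pmax(ins_len, 0L)), NA_character_)
    return(as.character(out))
  }
  subj <- Biostrings::DNAStringSet(gsub("[^ACGTN]", "N", sequence))
  lhits <- Biostrings::vmatchPattern(left_flank, subj,
                                     max.mismatch = max_mismatch)
  rhits <- Biostrings::vmatchPattern(right_flank, subj,
                                     max.mismatch = max_mismatch)
  vapply(seq_len(n), function(i) {
    ls <- Biostrings::startIndex(lhits)[[i]]
    if (is.null(ls) || length(ls) == 0L) return(NA_character_)
    ins_start <- min(ls) + nchar(left_flank)
    rs <- Biostrings::startIndex(rhits)[[i]]
    rs <- rs[rs >= ins_start]
    if (length(rs) == 0L) return(NA_character_)
    ins_end <- min(rs) - 1L
    if (ins_end < ins_start) return(NA_character_)
    substr(sequence[i], ins_start, ins_end)
  }, character(1))
}

#' Reverse complement of DNA sequences
#'
#' Batch converts sequences from reverse sequencing runs to their
#' reverse (Watson-Crick) complements; `N` maps to `N`.
#'
#' @param sequence Character vector over \{A, C, G, T, N\}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TGCGG") # "CCGCA"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  if (length(sequence) == 0L) return(character())
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence ", which(bad)[1L],
         " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Pre-process one selection round into a ranked unique-sequence table
#'
#' Runs the full pre-processing pipeline on one FASTQ file: ingest (first
#' `max_reads` records) -> quality filter -> trim (coordinates or
#' flanking primers; reads failing trimming are dropped and do not count
#' as high-quality) -> reverse complement if the run was sequenced in
#' reverse orientation -> dereplicate and rank. Reads made identical by
#' trimming are re-aggregated, so counts refer to the trimmed,
#' orientation-corrected region of interest.
#'
#' @param path FASTQ file for the round (plain, gzip or zip).
#' @param config A [preprocess_config()].
#' @param label Round label (e.g. `"round1"`); defaults to the file name.
#' @param max_reads Cap on raw records ingested (`Inf` = all).
#' @return A `round_table`: list with `label`, `entries` (tibble `rank`,
#'   `sequence`, `reads`), `total_reads` (records ingested), `hq_reads`
#'   (records surviving quality filter and trimming; equals the sum of
#'   `entries$reads`) and `unique_count`.
#' @export
preprocess_round <- function(path, config = preprocess_config(),
                             label = NULL, max_reads = Inf) {
  stopifnot(inherits(config, "preprocess_config"))
  if (is.null(label)) {
    label <- sub("\\.(fastq|fq)(\\.(gz|zip))?$", "", basename(path),
                 ignore.case = TRUE)
  }
  records <- read_fastq(path, max_reads = max_reads)
  total_reads <- nrow(records)
  kept <- quality_filter(records, config$quality_cutoff, config$q_threshold)
  seqs <- kept$sequence

  seqs <- switch(config$trim_mode,
    none = seqs,
    positions = trim_by_position(seqs, config$trim_start, config$trim_end),
    primers = trim_by_primers(seqs, config$fwd_primer, config$rev_flank,
                              config$primer_max_mismatch)
  )
  n_dropped <- sum(is.na(seqs))
  if (n_dropped > 0L) {
    message(label, ": ", n_dropped, " read(s) dropped at trimming")
  }
  seqs <- seqs[!is.na(seqs)]
  if (config$orientation == "reverse") {
    seqs <- reverse_complement(seqs)
  }
  entries <- dereplicate(seqs)
  round_table(label = label, entries = entries, total_reads = total_reads,
              hq_reads = length(seqs))
}

#' Construct a per-round table of counted unique sequences
#'
#' @param label Round label.
#' @param entries Tibble with columns `rank`, `sequence`, `reads`.
#' @param total_reads Raw records ingested for the round.
#' @param hq_reads Reads surviving quality filtering and trimming; must
#'   equal `sum(entries$reads)`.
#' @return A list of class `round_table`.
#' @export
round_table <- function(label, entries, total_reads, hq_reads) {
  stopifnot(is.data.frame(entries),
            all(c("rank", "sequence", "reads") %in% names(entries)))
  if (nrow(entries) > 0L) {
    stopifnot(all(entries$reads >= 1L),
              !is.unsorted(entries$rank),
              all(diff(entries$reads) <= 0L))
  }
  if (sum(entries$reads) != hq_reads) {
    stop("read-count conservation violated: sum(entries$reads) = ",
         sum(entries$reads), " but hq_reads = ", hq_reads, call. = FALSE)
  }
  stopifnot(hq_reads <= total_reads)
  structure(
    list(label = label, entries = entries,
         total_reads = as.integer(total_reads),
         hq_reads = as.integer(hq_reads),
         unique_count = nrow(entries)),
    class = "round_table"
  )
}

#' @export
print.round_table <- function(x, ...) {
  cat("<round_table> ", x$label, ": ", x$total_reads, " reads ingested, ",
      x$hq_reads, " high-quality, ", x$unique_count, " unique\n", sep = "")
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Export a pre-processed round as a spreadsheet
#'
#' Writes the ranked unique-sequence table of one round as CSV (columns
#' `rank`, `sequence`, `reads`), capped at the `cap` most abundant
#' entries (default 10,000).
#'
#' @param table A `round_table`.
#' @param path Output CSV path.
#' @param cap Maximum number of rows exported.
#' @return `path`, invisibly.
#' @export
export_round <- function(table, path, cap = 10000L) {
  stopifnot(inherits(table, "round_table"), cap >= 1)
  write_csv_table(utils::head(table$entries, cap), path)
}
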