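#' Read a FASTQ file of single-end reads
#'
#' Reads a 4-line-per-record FASTQ file (Sanger / Phred+33 quality
#' encoding), optionally gzip- or zip-compressed, and returns at most
#' `max_reads` records in file order. Compression is detected from the
#' file's magic bytes, falling back to the extension. A zip archive must
#' contain exactly one member, the FASTQ file for that selection round.
#'
#' The cap is applied at ingestion: the first `max_reads` raw records are
#' taken before any quality filtering. Analyzing such a subset (e.g. the
#' first 10,000 or 100,000 reads) preserves the identities and relative
#' abundances of the most abundant sequences while keeping run times low.
#'
#' @param path Path to a FASTQ file (`.fastq`, `.fq`, `.fastq.gz`,
#'   `.fastq.zip`, ...).
#' @param max_reads Maximum number of records to read (`Inf` = all).
#' @return A tibble of class `seq_records` with columns `read_id`,
#'   `sequence` and `quality` (one row per read, in file order).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, max_reads = Inf) {
  if (!file.exists(path)) {
    stop("cannot read FASTQ file: '", path, "' does not exist", call. = FALSE)
  }
  stopifnot(length(max_reads) == 1L, is.numeric(max_reads), max_reads >= 0)

  path <- resolve_container(path)
  con <- open_maybe_gzip(path)
  on.exit(close(con), add = TRUE)

  n_lines <- if (is.finite(max_reads)) 4L * as.integer(max_reads) else -1L
  lines <- readLines(con, n = n_lines, warn = FALSE)
  parse_fastq_lines(lines, source = path)
}

#' @keywords internal
parse_fastq_lines <- function(lines, source = "<fastq>") {
  n <- length(lines)
  if (n == 0L) {
    return(new_seq_records(character(), character(), character()))
  }
  if (n %% 4L != 0L) {
    stop(
      "malformed FASTQ in '", source, "': line count (", n,
      ") is not a multiple of 4; record ", n %/% 4L + 1L, " is incomplete",
      call. = FALSE
    )
  }
  idx <- seq_len(n %/% 4L)
  headers <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  quals <- lines[4L * idx]

  bad_hdr <- which(!startsWith(headers, "@"))
  if (length(bad_hdr) > 0L) {
    stop("malformed FASTQ in '", source, "': record ", bad_hdr[1L],
         " does not start with '@'", call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    stop("malformed FASTQ in '", source, "': record ", bad_plus[1L],
         " lacks the '+' separator line", call. = FALSE)
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len) > 0L) {
    stop(
      "malformed FASTQ in '", source, "': record ", bad_len[1L],
      " has sequence length ", nchar(seqs[bad_len[1L]]),
      " but quality length ", nchar(quals[bad_len[1L]]),
      call. = FALSE
    )
  }
  new_seq_records(sub("^@", "", headers), toupper(seqs), quals)
}

new_seq_records <- function(read_id, sequence, quality) {
  out <- tibble::tibble(read_id = read_id, sequence = sequence,
                        quality = quality)
  class(out) <- c("seq_records", class(out))
  out
}

# Detect container format; a zip archive is extracted to a temp dir and
# must hold exactly one member.
resolve_container <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  is_zip <- length(magic) >= 4L &&
    identical(magic[1:2], as.raw(c(0x50, 0x4b))) ||
    grepl("\\.zip$", path, ignore.case = TRUE)
  if (!is_zip) {
    return(path)
  }
  members <- utils::unzip(path, list = TRUE)$Name
  members <- members[!grepl("/$", members)]
  if (length(members) != 1L) {
    stop("zip archive '", path, "' must contain exactly one FASTQ file, ",
         "found ", length(members), call. = FALSE)
  }
  exdir <- tempfile("selexr_unzip_")
  utils::unzip(path, files = members, exdir = exdir, junkpaths = TRUE)
  file.path(exdir, basename(members))
}

open_maybe_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

#' Decode a Phred+33 quality string
#'
#' Converts the quality line of a FASTQ record into integer Q scores,
#' `Q[i] = ASCII(quality[i]) - 33`. Q is -10*log10 of the base-calling
#' error probability, so Q20 corresponds to a 1% error rate.
#'
#' @param quality A quality string (characters in ASCII 33..126).
#' @return Integer vector of Q scores, one per base.
#' @examples
#' decode_phred("I5?!") # 40 20 30 0
#' @export
decode_phred <- function(quality) {
  stopifnot(is.character(quality), length(quality) == 1L)
  q <- utf8ToInt(quality) - 33L
  if (length(q) > 0L && min(q) < 0L) {
    stop("invalid Phred+33 quality string: character below ASCII 33 at ",
         "position ", which.min(q), call. = FALSE)
  }
  q
}

#' Write a table to CSV
#'
#' Writes any of the package's tabular outputs as an RFC-4180 CSV file
#' (UTF-8, header row, rows in input order). All spreadsheets produced
#' by the pipeline go through this function so output is deterministic.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write sequence records back to FASTQ
#'
#' Inverse of [read_fastq()] for uncompressed output; reading then
#' re-serializing a well-formed file reproduces its records byte for
#' byte.
#'
#' @param records A `seq_records` tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "sequence", "quality") %in% names(records)))
  lines <- as.vector(rbind(paste0("@", records$read_id), records$sequence,
                           "+", records$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}
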