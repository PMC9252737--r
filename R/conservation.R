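#' Per-position nucleotide conservation of a sequence cluster
#'
#' Quantifies the distribution of the four nucleotides at each position
#' across the members of a cluster. Positions where one base dominates
#' are conserved and likely matter for the selected function; variable
#' positions tolerate mutation. By default each member is weighted by
#' its read count, so the profile reflects the selected population;
#' `weighted = FALSE` counts each unique sequence once. Ambiguous `N`
#' base calls are excluded from both numerator and denominator at their
#' position.
#'
#' @param cluster Tibble of cluster members with columns `sequence` and
#'   `reads` (see [cluster_members()]), all sequences of equal length.
#' @param weighted Weight members by read count (default `TRUE`).
#' @return A list of class `conservation_matrix`: `freq` (L x 4 matrix,
#'   columns A, C, G, T; rows sum to 1 where defined), `weighted`,
#'   `n_sequences`, `n_reads`.
#' @export
conservation_matrix <- function(cluster, weighted = TRUE) {
  stopifnot(is.data.frame(cluster),
            all(c("sequence", "reads") %in% names(cluster)),
            nrow(cluster) > 0L)
  lens <- unique(nchar(cluster$sequence))
  if (length(lens) != 1L) {
    stop("cluster members differ in length (", paste(lens, collapse = ", "),
         "); re-cluster with the hamming metric or trim reads to a fixed ",
         "window first", call. = FALSE)
  }
  L <- lens
  w <- if (weighted) as.numeric(cluster$reads) else rep(1, nrow(cluster))
  chars <- matrix(unlist(strsplit(cluster$sequence, ""), use.names = FALSE),
                  nrow = nrow(cluster), ncol = L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = L, ncol = 4L,
                 dimnames = list(NULL, bases))
  for (b in bases) {
    freq[, b] <- colSums((chars == b) * w)
  }
  denom <- rowSums(freq) # N bases drop out of numerator and denominator
  defined <- denom > 0
  freq[defined, ] <- freq[defined, , drop = FALSE] / denom[defined]
  structure(
    list(freq = freq, weighted = weighted, n_sequences = nrow(cluster),
         n_reads = sum(cluster$reads)),
    class = "conservation_matrix"
  )
}

# tied base sets -> IUPAC ambiguity code (inverse of the standard
# code -> base-set expansion)
iupac_code_for <- function(bases) {
  sets <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(bases), collapse = "")
  hit <- names(sets)[vapply(strsplit(sets, ""), function(s) {
    identical(sort(s), sort(bases))
  }, logical(1))]
  if (length(hit) == 0L) {
    stop("no IUPAC code for base set {", key, "}", call. = FALSE)
  }
  hit[1L]
}

#' Consensus sequence and information-content logo data
#'
#' Derives from a conservation matrix: the consensus sequence (the
#' per-position majority base; ties become the IUPAC ambiguity code of
#' the tied set), the per-position Shannon information content in bits
#' (`2 + sum_b f log2 f`, with 0*log0 = 0; 2 bits = perfectly
#' conserved, 0 bits = uniform), and letter heights (frequency times
#' information) for rendering a sequence logo. No small-sample
#' correction is applied.
#'
#' @param matrix A [conservation_matrix()] result.
#' @return A list of class `consensus_logo`: `consensus` (string of
#'   length L), `info_bits` (numeric, in \[0, 2\]), `letter_heights`
#'   (L x 4 matrix; each row sums to its `info_bits`).
#' @export
consensus_and_logo <- function(matrix) {
  stopifnot(inherits(matrix, "conservation_matrix"))
  freq <- matrix$freq
  L <- nrow(freq)
  bases <- colnames(freq)
  consensus <- character(L)
  info <- numeric(L)
  for (i in seq_len(L)) {
    row <- freq[i, ]
    top <- bases[row == max(row) & row > 0]
    consensus[i] <- if (length(top) == 0L) {
      "N" # position seen only as ambiguous calls
    } else if (length(top) == 1L) {
      top
    } else {
      iupac_code_for(top)
    }
    p <- row[row > 0]
    info[i] <- 2 + sum(p * log2(p))
  }
  heights <- freq * info
  structure(
    list(consensus = paste(consensus, collapse = ""), info_bits = info,
         letter_heights = heights),
    class = "consensus_logo"
  )
}

#' @export
print.consensus_logo <- function(x, ...) {
  cat("<consensus_logo> consensus:", x$consensus, "\n")
  cat("mean information:", round(mean(x$info_bits), 3), "bits\n")
  invisible(x)
}

#' Conservation matrix as a plot-ready table
#'
#' Long-format export of a conservation matrix (heatmap data): one row
#' per position per base with the base's frequency.
#'
#' @param matrix A [conservation_matrix()] result.
#' @return Tibble `position`, `base`, `frequency`.
#' @export
conservation_table <- function(matrix) {
  stopifnot(inherits(matrix, "conservation_matrix"))
  freq <- matrix$freq
  tibble::tibble(
    position = rep(seq_len(nrow(freq)), times = ncol(freq)),
    base = rep(colnames(freq), each = nrow(freq)),
    frequency = as.vector(freq)
  )
}

#' Logo letter heights as a plot-ready table
#'
#' @param logo A [consensus_and_logo()] result.
#' @return Tibble `position`, `base`, `height` (frequency x information
#'   content, bits).
#' @export
logo_table <- function(logo) {
  stopifnot(inherits(logo, "consensus_logo"))
  h <- logo$letter_heights
  tibble::tibble(
    position = rep(seq_len(nrow(h)), times = ncol(h)),
    base = rep(colnames(h), each = nrow(h)),
    height = as.vector(h)
  )
}
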