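#' Bundle pre-processed rounds into a selection series
#'
#' A selection series is an ordered list of per-round tables, in
#' selection order (round 1 first). At most ten rounds can be analyzed
#' at once; for longer experiments, analyze representative rounds.
#'
#' @param ... `round_table` objects, or a single list of them.
#' @return A list of class `selection_series`.
#' @export
selection_series <- function(...) {
  rounds <- list(...)
  if (length(rounds) == 1L && !inherits(rounds[[1L]], "round_table")) {
    rounds <- rounds[[1L]]
  }
  ok <- vapply(rounds, inherits, logical(1), what = "round_table")
  if (!all(ok)) {
    stop("all elements must be round_table objects", call. = FALSE)
  }
  if (length(rounds) < 1L || length(rounds) > 10L) {
    stop("a selection series holds between 1 and 10 rounds, got ",
         length(rounds), call. = FALSE)
  }
  names(rounds) <- vapply(rounds, `[[`, character(1), "label")
  structure(rounds, class = "selection_series")
}

#' @export
print.selection_series <- function(x, ...) {
  cat("<selection_series> with", length(x), "round(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Per-round selection statistics
#'
#' Summarizes each round: total reads ingested, high-quality reads,
#' unique sequences, and the fraction of unique sequences
#' (`unique_count / hq_reads`). A decline of the unique-sequence
#' fraction across rounds indicates sequence enrichment and usually
#' accompanies functional enrichment.
#'
#' @param series A [selection_series()].
#' @return A tibble with one row per round: `label`, `total_reads`,
#'   `hq_reads`, `unique_count`, `fraction_unique`.
#' @export
selection_statistics <- function(series) {
  stopifnot(inherits(series, "selection_series"))
  rows <- lapply(series, function(rt) {
    frac <- if (rt$hq_reads > 0L) rt$unique_count / rt$hq_reads else NA_real_
    tibble::tibble(label = rt$label, total_reads = rt$total_reads,
                   hq_reads = rt$hq_reads, unique_count = rt$unique_count,
                   fraction_unique = frac)
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$fraction_unique)) {
    warning("fraction_unique is undefined for rounds with no ",
            "high-quality reads", call. = FALSE)
  }
  out
}

#' The N most abundant sequences of a round
#'
#' Returns the top `n` unique sequences of a round (typically the final
#' round) with their read counts — the usual shortlist for biochemical
#' characterization. Ties in read count are resolved by the table's
#' deterministic lexicographic rank order.
#'
#' @param table A `round_table`.
#' @param n Number of sequences requested.
#' @return Tibble `rank`, `sequence`, `reads` with
#'   `min(n, unique_count)` rows.
#' @export
top_sequences <- function(table, n) {
  stopifnot(inherits(table, "round_table"), n >= 1)
  utils::head(table$entries, n)
}

#' Track fractional abundance of sequences across rounds
#'
#' For each target sequence, computes its fractional abundance in every
#' round: reads attributed to the sequence divided by the round's
#' high-quality read total, 0 when absent. Plotting these tracks shows
#' when enrichment becomes evident along the selection trajectory.
#'
#' @param series A [selection_series()].
#' @param targets Character vector of sequences to track.
#' @return A tibble with columns `sequence`, `round`, `label`,
#'   `fraction` (long format, one row per target per round).
#' @export
track_sequences <- function(series, targets) {
  stopifnot(inherits(series, "selection_series"),
            is.character(targets), length(targets) > 0L)
  rows <- lapply(seq_along(series), function(i) {
    rt <- series[[i]]
    m <- match(targets, rt$entries$sequence)
    reads <- ifelse(is.na(m), 0L, rt$entries$reads[m])
    frac <- if (rt$hq_reads > 0L) reads / rt$hq_reads else NA_real_
    tibble::tibble(sequence = targets, round = i, label = rt$label,
                   fraction = frac)
  })
  dplyr::bind_rows(rows)
}

#' Reshape an abundance track to a sequences-by-rounds matrix
#'
#' Convenience for exporting plot-ready matrices: rows are sequences
#' (or one motif row), columns are round labels.
#'
#' @param track Output of [track_sequences()] or [track_motif()]'s
#'   `track` element.
#' @return A tibble, first column `sequence`, one column per round.
#' @export
track_matrix <- function(track) {
  stopifnot(all(c("sequence", "label", "fraction") %in% names(track)))
  labs <- unique(track$label)
  seqs <- unique(track$sequence)
  wide <- matrix(0, nrow = length(seqs), ncol = length(labs),
                 dimnames = list(NULL, labs))
  wide[cbind(match(track$sequence, seqs), match(track$label, labs))] <-
    track$fraction
  dplyr::bind_cols(tibble::tibble(sequence = seqs),
                   tibble::as_tibble(wide))
}

# IUPAC nucleotide codes -> the set of concrete read bases each matches.
# A read 'N' (an ambiguous base call) satisfies only the pattern code N,
# never a concrete or partially degenerate code.
iupac_match_sets <- function() {
  base <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T", "N")
  )
  base
}

# 5-bit encoding of read bases A/C/G/T/N for mask-based matching
encode_bases <- function(chars) {
  lut <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
  out <- lut[chars]
  if (anyNA(out)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  unname(out)
}

pattern_masks <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) == 0L) {
    stop("motif pattern must be non-empty", call. = FALSE)
  }
  sets <- iupac_match_sets()
  chars <- strsplit(toupper(pattern), "")[[1L]]
  bad <- !(chars %in% names(sets))
  if (any(bad)) {
    stop("invalid IUPAC code '", chars[which(bad)[1L]],
         "' in motif pattern", call. = FALSE)
  }
  lut <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
  vapply(sets[chars], function(s) sum(lut[s]), numeric(1), USE.NAMES = FALSE)
}

#' Match a degenerate sequence motif against sequences
#'
#' Tests whether each sequence contains a contiguous window matching an
#' IUPAC degenerate motif (A/C/G/T/U plus ambiguity codes; U is treated
#' as T; R = purine, Y = pyrimidine, N = any base). Matching is
#' position-wise over the code's base set. An `N` in a read — an
#' ambiguous base call — matches only the pattern code `N`, so
#' uncertain bases are never counted as evidence for a concrete motif.
#'
#' @param sequence Character vector of reads over \{A, C, G, T, N\}.
#' @param pattern A single IUPAC motif string, e.g. `"TGCGG"` or
#'   `"RYN"`.
#' @return Logical vector, one element per sequence.
#' @examples
#' match_motif(c("AATGCGGTT", "TGCGA"), "TGCGG") # TRUE FALSE
#' @export
match_motif <- function(sequence, pattern) {
  masks <- pattern_masks(pattern)
  m <- length(masks)
  vapply(sequence, function(s) {
    L <- nchar(s)
    if (L < m) return(FALSE)
    enc <- encode_bases(strsplit(s, "")[[1L]])
    hit <- rep(TRUE, L - m + 1L)
    for (j in seq_len(m)) {
      hit <- hit & bitwAnd(enc[j:(L - m + j)], masks[j]) > 0L
      if (!any(hit)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Track a sequence motif across selection rounds
#'
#' For each round, extracts the unique sequences containing the motif
#' (a per-round spreadsheet) and computes the fraction of high-quality
#' reads carried by motif-containing sequences. Enrichment of a motif
#' across rounds suggests it contributes to the selected function.
#'
#' @param series A [selection_series()].
#' @param pattern An IUPAC motif string (see [match_motif()]).
#' @return A list with `per_round` (named list of tibbles `rank`,
#'   `sequence`, `reads`, one per round) and `track` (tibble `sequence`
#'   = the motif, `round`, `label`, `fraction`).
#' @export
track_motif <- function(series, pattern) {
  stopifnot(inherits(series, "selection_series"))
  per_round <- lapply(series, function(rt) {
    hit <- if (nrow(rt$entries) > 0L) {
      match_motif(rt$entries$sequence, pattern)
    } else {
      logical()
    }
    rt$entries[hit, , drop = FALSE]
  })
  frac <- vapply(seq_along(series), function(i) {
    rt <- series[[i]]
    if (rt$hq_reads == 0L) return(NA_real_)
    sum(per_round[[i]]$reads) / rt$hq_reads
  }, numeric(1))
  track <- tibble::tibble(sequence = pattern,
                          round = seq_along(series),
                          label = names(series), fraction = frac)
  list(per_round = per_round, track = track)
}

#' Hamming distance between equal-length sequences
#'
#' Number of mismatching positions between two strings of equal length.
#'
#' @param a,b Sequences to compare (vectorized; recycled as in
#'   element-wise comparison of equal-length vectors).
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  }, a, b, USE.NAMES = FALSE)
}

#' Find mutational intermediates between two sequences
#'
#' Searches all rounds for observed sequences that lie in the sequence
#' space between `source` and `target` on the Hamming hypercube: an
#' intermediate agrees with both at every position where they agree and
#' carries the source or the target base at each differing position
#' (and is neither endpoint). Every intermediate m therefore satisfies
#' `hamming(m, source) + hamming(m, target) == hamming(source, target)`.
#' The tool then searches for neutral paths: chains of single point
#' mutations from source to target whose every interior sequence was
#' observed in the data. Such paths exist only if all required
#' intermediates are present.
#'
#' A relaxed mode (`max_extra_mutations > 0`) additionally reports
#' observed sequences that deviate from strict betweenness at up to
#' that many positions; these are flagged `strict = FALSE` and excluded
#' from path search.
#'
#' @param series A [selection_series()].
#' @param source,target Equal-length, distinct nucleotide strings.
#' @param max_paths Cap on the number of neutral paths returned
#'   (default 100).
#' @param max_extra_mutations Extra (off-betweenness) mutations allowed
#'   in reported intermediates (default 0 = strict).
#' @return A list of class `intermediate_result` with elements
#'   `source`, `target`, `differing_positions`, `intermediates` (tibble
#'   `sequence`, per-round read-count columns, `hamming_to_source`,
#'   `hamming_to_target`, `strict`) and `paths` (list of character
#'   vectors `source, ..., target`).
#' @export
find_intermediates <- function(series, source, target, max_paths = 100L,
                               max_extra_mutations = 0L) {
  stopifnot(inherits(series, "selection_series"))
  if (nchar(source) != nchar(target)) {
    stop("source and target must have equal length", call. = FALSE)
  }
  if (source == target) {
    stop("source and target must differ", call. = FALSE)
  }
  src <- strsplit(source, "")[[1L]]
  tgt <- strsplit(target, "")[[1L]]
  L <- length(src)
  diff_pos <- which(src != tgt)
  d <- length(diff_pos)

  observed <- unique(unlist(lapply(series, function(rt) rt$entries$sequence),
                            use.names = FALSE))
  observed <- observed[nchar(observed) == L]
  observed <- setdiff(observed, c(source, target))

  extra <- vapply(observed, function(s) {
    ch <- strsplit(s, "")[[1L]]
    off <- sum(ch[-diff_pos] != src[-diff_pos])
    third <- sum(ch[diff_pos] != src[diff_pos] & ch[diff_pos] != tgt[diff_pos])
    off + third
  }, numeric(1), USE.NAMES = FALSE)
  keep <- extra <= max_extra_mutations
  inter <- observed[keep]
  strict <- extra[keep] == 0

  counts <- lapply(series, function(rt) {
    m <- match(inter, rt$entries$sequence)
    ifelse(is.na(m), 0L, rt$entries$reads[m])
  })
  names(counts) <- paste0("reads_", names(series))

  tab <- tibble::tibble(sequence = inter)
  for (nm in names(counts)) tab[[nm]] <- counts[[nm]]
  tab$hamming_to_source <- if (length(inter)) hamming(inter, source) else integer()
  tab$hamming_to_target <- if (length(inter)) hamming(inter, target) else integer()
  tab$strict <- strict
  ord <- order(tab$hamming_to_source, rank_c_locale(tab$sequence))
  tab <- tab[ord, , drop = FALSE]

  paths <- enumerate_neutral_paths(source, target,
                                   tab$sequence[tab$strict], max_paths)
  structure(
    list(source = source, target = target, differing_positions = diff_pos,
         intermediates = tab, paths = paths),
    class = "intermediate_result"
  )
}

# Breadth-first layered enumeration of Hamming-1 chains source -> target
# through the given strict intermediates. Betweenness makes the graph a
# DAG layered by distance from source, so every chain has length d and
# all returned paths are shortest. Nodes that cannot reach the target
# are removed by a backward sweep first, so the path cap never hides an
# existing path.
enumerate_neutral_paths <- function(source, target, intermediates,
                                    max_paths) {
  d <- hamming(source, target)
  if (d == 1L) {
    return(list(c(source, target)))
  }
  layers <- lapply(seq_len(d - 1L), function(h) {
    intermediates[hamming(intermediates, source) == h]
  })
  if (any(vapply(layers, length, integer(1)) == 0L)) return(list())

  # backward sweep: keep only nodes with a Hamming-1 successor that
  # reaches the target
  nxt <- target
  for (h in rev(seq_len(d - 1L))) {
    viable <- layers[[h]][vapply(layers[[h]], function(s) {
      any(hamming(rep(s, length(nxt)), nxt) == 1L)
    }, logical(1))]
    if (length(viable) == 0L) return(list())
    layers[[h]] <- viable
    nxt <- viable
  }
  if (!any(hamming(rep(source, length(layers[[1L]])), layers[[1L]]) == 1L)) {
    return(list())
  }

  # forward enumeration over viable nodes only; every partial path is
  # completable, so truncation at max_paths is safe
  partial <- list(source)
  for (h in seq_len(d - 1L)) {
    nodes <- layers[[h]]
    nxt_paths <- list()
    for (p in partial) {
      tip <- p[length(p)]
      step <- nodes[hamming(rep(tip, length(nodes)), nodes) == 1L]
      for (s in step) {
        if (length(nxt_paths) >= max_paths) break
        nxt_paths[[length(nxt_paths) + 1L]] <- c(p, s)
      }
      if (length(nxt_paths) >= max_paths) break
    }
    partial <- nxt_paths
    if (length(partial) == 0L) return(list())
  }
  lapply(partial, function(p) c(p, target))
}

#' @export
print.intermediate_result <- function(x, ...) {
  cat("<intermediate_result> ", x$source, " -> ", x$target, " (",
      length(x$differing_positions), " differing positions)\n",
      nrow(x$intermediates), " intermediate(s), ", length(x$paths),
      " neutral path(s)\n", sep = "")
  invisible(x)
}
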