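#' Cluster closely related sequences around abundance peaks
#'
#' Greedy abundance-seeded clustering: the most abundant unassigned
#' sequence seeds a cluster (its peak), and every unassigned sequence
#' within `max_edit_distance` of that seed joins it; this repeats up to
#' `k` times or until all sequences are assigned. Closely related
#' nucleic acid sequences usually adopt similar structures, so each
#' cluster approximates one functional sequence family and its peak is
#' the family's representative for biochemical characterization.
#' Sequences still unassigned after `k` seeds are reported as
#' unclustered.
#'
#' Clusters are numbered from 0 in seed order, so peak read counts are
#' non-increasing in cluster id and the peak of cluster 0 is always the
#' globally most abundant sequence. Because a later seed can still
#' gather more total reads, each cluster also carries a `mass_rank`
#' (1 = largest total member reads, ties broken by peak reads then peak
#' sequence); cluster rank R in conservation analysis refers to this
#' mass ranking.
#'
#' @param table A `round_table` (typically the final round; clustering
#'   is the most expensive step, so it is usually run on one round).
#' @param k Number of clusters to seed (1..50).
#' @param max_edit_distance Levenshtein radius around each peak
#'   (default 7, roughly the mutational load expected of an enriched
#'   family on a 40-nt region); 0 makes every unique sequence its own
#'   cluster.
#' @param metric `"levenshtein"` (tolerates indels; default) or
#'   `"hamming"` (equal-length sequences only).
#' @return A list of class `seq_clustering` with `clusters` (tibble
#'   `cluster_id`, `peak`, `peak_reads`, `n_members`, `total_reads`,
#'   `mass_rank`), `members` (tibble `cluster_id`, `member_rank`,
#'   `sequence`, `reads`), `unclustered` (tibble `sequence`, `reads`)
#'   and `params`.
#' @export
cluster_sequences <- function(table, k, max_edit_distance = 7L,
                              metric = c("levenshtein", "hamming")) {
  stopifnot(inherits(table, "round_table"))
  metric <- match.arg(metric)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > 50) stop("at most 50 clusters can be requested", call. = FALSE)
  stopifnot(max_edit_distance >= 0)
  entries <- table$entries
  if (nrow(entries) == 0L) stop("round table is empty", call. = FALSE)
  if (metric == "hamming" && length(unique(nchar(entries$sequence))) > 1L) {
    stop("hamming metric requires equal-length sequences; use ",
         "levenshtein or trim first", call. = FALSE)
  }

  unassigned <- seq_len(nrow(entries)) # in rank order
  assignments <- vector("list", k)
  n_clusters <- 0L
  for (i in seq_len(k)) {
    if (length(unassigned) == 0L) break
    seed_idx <- unassigned[1L] # highest rank among unassigned
    dists <- seq_distance(entries$sequence[seed_idx],
                          entries$sequence[unassigned], metric)
    members <- unassigned[dists <= max_edit_distance]
    n_clusters <- i
    assignments[[i]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  assignments <- assignments[seq_len(n_clusters)]

  summaries <- lapply(assignments, function(members) {
    sub <- entries[members, , drop = FALSE] # already reads-desc, tie-broken
    list(peak = sub$sequence[1L], peak_reads = sub$reads[1L],
         n_members = nrow(sub), total_reads = sum(sub$reads), sub = sub)
  })
  mass_ord <- order(-vapply(summaries, `[[`, numeric(1), "total_reads"),
                    -vapply(summaries, `[[`, numeric(1), "peak_reads"),
                    rank_c_locale(vapply(summaries, `[[`, character(1),
                                         "peak")))
  mass_rank <- integer(length(summaries))
  mass_rank[mass_ord] <- seq_along(summaries)

  clusters <- dplyr::bind_rows(lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    tibble::tibble(cluster_id = i - 1L, peak = s$peak,
                   peak_reads = s$peak_reads, n_members = s$n_members,
                   total_reads = s$total_reads, mass_rank = mass_rank[i])
  }))
  members <- dplyr::bind_rows(lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    tibble::tibble(cluster_id = i - 1L,
                   member_rank = seq_len(nrow(s$sub)),
                   sequence = s$sub$sequence, reads = s$sub$reads)
  }))
  unclust <- entries[unassigned, c("sequence", "reads"), drop = FALSE]

  structure(
    list(clusters = clusters, members = members, unclustered = unclust,
         params = list(k_requested = as.integer(k),
                       max_edit_distance = as.integer(max_edit_distance),
                       metric = metric, source_label = table$label,
                       hq_reads = table$hq_reads)),
    class = "seq_clustering"
  )
}

seq_distance <- function(ref, seqs, metric) {
  if (metric == "levenshtein") {
    as.integer(utils::adist(ref, seqs))
  } else {
    hamming(rep(ref, length(seqs)), seqs)
  }
}

#' @export
print.seq_clustering <- function(x, ...) {
  cat("<seq_clustering> ", nrow(x$clusters), " cluster(s) (radius ",
      x$params$max_edit_distance, ", ", x$params$metric, "), ",
      nrow(x$unclustered), " unclustered sequence(s)\n", sep = "")
  print(utils::head(x$clusters, 5))
  invisible(x)
}

#' Peak sequences of the most abundant clusters
#'
#' Returns the peak sequence (most abundant member) and its read count
#' for each of the first `n` clusters in cluster order.
#'
#' @param clustering A [cluster_sequences()] result.
#' @param n Number of clusters requested.
#' @return Tibble `cluster_id`, `peak`, `peak_reads`.
#' @export
cluster_peaks <- function(clustering, n) {
  stopifnot(inherits(clustering, "seq_clustering"), n >= 1)
  utils::head(clustering$clusters[, c("cluster_id", "peak", "peak_reads")], n)
}

#' Export cluster memberships as a spreadsheet table
#'
#' Flattens a clustering into rows (`cluster_id`, `member_rank`,
#' `sequence`, `reads`): clusters in order, members by reads
#' descending, truncated to `member_cap` rows in total (default 1000).
#'
#' @param clustering A [cluster_sequences()] result.
#' @param member_cap Maximum number of rows (>= 1).
#' @return A tibble of at most `member_cap` rows.
#' @export
export_clusters <- function(clustering, member_cap = 1000L) {
  stopifnot(inherits(clustering, "seq_clustering"), member_cap >= 1)
  utils::head(clustering$members, member_cap)
}

#' Track cluster peak abundances across rounds
#'
#' Tracks the fractional abundance of the peak sequences of the `n`
#' most abundant clusters across all rounds of a series (see
#' [track_sequences()]). Like tracking top sequences, this reveals when
#' each sequence family was enriched, before activity is detectable in
#' pools.
#'
#' @param series A [selection_series()].
#' @param clustering A clustering computed on one round of the series
#'   (typically the last).
#' @param n Number of clusters whose peaks to track.
#' @return A tibble as from [track_sequences()].
#' @export
track_cluster_peaks <- function(series, clustering, n) {
  peaks <- cluster_peaks(clustering, n)
  track_sequences(series, peaks$peak)
}

#' Extract one cluster by abundance rank
#'
#' Convenience accessor: cluster rank R = 1 denotes the most abundant
#' cluster (largest total member reads), R = 2 the second most
#' abundant, and so on — the ranking used to pick a cluster for
#' conservation analysis.
#'
#' @param clustering A [cluster_sequences()] result.
#' @param rank Cluster rank R (1-based, by total member reads).
#' @return Tibble of the cluster's members (`sequence`, `reads`).
#' @export
cluster_members <- function(clustering, rank) {
  stopifnot(inherits(clustering, "seq_clustering"),
            rank >= 1, rank <= nrow(clustering$clusters))
  id <- clustering$clusters$cluster_id[clustering$clusters$mass_rank == rank]
  clustering$members[clustering$members$cluster_id == id,
                     c("sequence", "reads"), drop = FALSE]
}
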