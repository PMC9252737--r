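#' Configuration for a full pipeline run
#'
#' Collects everything one analysis run needs: the per-round FASTQ
#' files (uploaded once; every tool then works from the cached
#' pre-processed tables), pre-processing parameters, which tools to
#' run, their parameters, and the output directory.
#'
#' @param inputs Character vector of 1..10 FASTQ paths, in selection
#'   order.
#' @param labels Round labels (default `round1`, `round2`, ...).
#' @param preprocess A [preprocess_config()].
#' @param max_reads Cap on raw records ingested per file (`Inf` = all).
#' @param tools Character vector of tools to run, any of `"stats"`,
#'   `"top"`, `"track"`, `"motif"`, `"intermediates"`, `"cluster"`,
#'   `"peaks"`, `"peak-track"`, `"conservation"`; pre-processed tables
#'   are always exported.
#' @param n Number of top sequences / cluster peaks (default 5).
#' @param k Number of clusters to seed (default 10).
#' @param max_edit_distance Clustering radius (default 7).
#' @param motif IUPAC motif string (required for the motif tool).
#' @param source,target Sequences for the intermediates tool.
#' @param cluster_rank Cluster rank R for conservation analysis
#'   (default 1 = most abundant cluster).
#' @param weighted Weight conservation by read counts (default `TRUE`).
#' @param member_cap Row cap for the cluster membership export
#'   (default 1000).
#' @param outdir Output directory for CSVs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs,
                       labels = NULL,
                       preprocess = preprocess_config(),
                       max_reads = Inf,
                       tools = c("stats", "top", "track"),
                       n = 5L, k = 10L, max_edit_distance = 7L,
                       motif = NULL, source = NULL, target = NULL,
                       cluster_rank = 1L, weighted = TRUE,
                       member_cap = 1000L,
                       outdir = "selexr_output") {
  stopifnot(is.character(inputs), length(inputs) >= 1L,
            length(inputs) <= 10L,
            inherits(preprocess, "preprocess_config"))
  known <- c("stats", "top", "track", "motif", "intermediates",
             "cluster", "peaks", "peak-track", "conservation")
  bad <- setdiff(tools, known)
  if (length(bad) > 0L) {
    stop("unknown tool(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("round", seq_along(inputs))
  stopifnot(length(labels) == length(inputs))
  structure(
    list(inputs = inputs, labels = labels, preprocess = preprocess,
         max_reads = max_reads, tools = tools, n = as.integer(n),
         k = as.integer(k),
         max_edit_distance = as.integer(max_edit_distance),
         motif = motif, source = source, target = target,
         cluster_rank = as.integer(cluster_rank), weighted = weighted,
         member_cap = as.integer(member_cap), outdir = outdir),
    class = "run_config"
  )
}

#' Run the analysis pipeline end to end
#'
#' Pre-processes every input FASTQ once, caches the per-round tables,
#' then runs the requested tools against the cache and writes each
#' tool's spreadsheet(s) to `outdir`. Output is deterministic: the same
#' config yields byte-identical CSVs. Per-round tables are exported
#' capped at their 10,000 most abundant entries.
#'
#' Files written (when the corresponding tool is selected):
#' `preprocessed_<label>.csv`, `selection_statistics.csv`,
#' `top_sequences.csv`, `top_sequence_track.csv`,
#' `motif_<label>.csv` + `motif_track.csv`,
#' `intermediates.csv` + `neutral_paths.csv`,
#' `cluster_peaks.csv` + `cluster_members.csv`,
#' `cluster_peak_track.csv`,
#' `conservation_matrix.csv` + `consensus_logo.csv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cached `series`, computed tool
#'   results, and `manifest` (character vector of files written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  manifest <- character()
  emit <- function(rows, name) {
    write_csv_table(rows, out(name))
    manifest <<- c(manifest, out(name))
  }

  # single ingestion: every tool below reuses these cached tables
  rounds <- lapply(seq_along(config$inputs), function(i) {
    rt <- preprocess_round(config$inputs[i], config$preprocess,
                           label = config$labels[i],
                           max_reads = config$max_reads)
    message(rt$label, ": ", rt$total_reads, " reads, ", rt$hq_reads,
            " high-quality, ", rt$unique_count, " unique")
    rt
  })
  series <- selection_series(rounds)
  final <- series[[length(series)]]
  for (rt in series) {
    emit(utils::head(rt$entries, 10000L),
         paste0("preprocessed_", rt$label, ".csv"))
  }

  results <- list(series = series)
  tools <- config$tools

  if ("stats" %in% tools) {
    results$statistics <- selection_statistics(series)
    emit(results$statistics, "selection_statistics.csv")
  }
  if ("top" %in% tools) {
    results$top <- top_sequences(final, config$n)
    emit(results$top, "top_sequences.csv")
  }
  if ("track" %in% tools) {
    top <- top_sequences(final, config$n)
    results$track <- track_sequences(series, top$sequence)
    emit(track_matrix(results$track), "top_sequence_track.csv")
  }
  if ("motif" %in% tools) {
    if (is.null(config$motif)) {
      stop("the motif tool requires a motif pattern", call. = FALSE)
    }
    mt <- track_motif(series, config$motif)
    results$motif <- mt
    for (lab in names(mt$per_round)) {
      emit(mt$per_round[[lab]], paste0("motif_", lab, ".csv"))
    }
    emit(mt$track, "motif_track.csv")
  }
  if ("intermediates" %in% tools) {
    if (is.null(config$source) || is.null(config$target)) {
      stop("the intermediates tool requires source and target sequences",
           call. = FALSE)
    }
    ir <- find_intermediates(series, config$source, config$target)
    results$intermediates <- ir
    emit(ir$intermediates, "intermediates.csv")
    paths_tab <- if (length(ir$paths) == 0L) {
      tibble::tibble(path = integer(), step = integer(),
                     sequence = character())
    } else {
      dplyr::bind_rows(lapply(seq_along(ir$paths), function(i) {
        tibble::tibble(path = i, step = seq_along(ir$paths[[i]]),
                       sequence = ir$paths[[i]])
      }))
    }
    emit(paths_tab, "neutral_paths.csv")
  }

  needs_clustering <- any(c("cluster", "peaks", "peak-track",
                            "conservation") %in% tools)
  if (needs_clustering) {
    cl <- cluster_sequences(final, config$k, config$max_edit_distance)
    results$clustering <- cl
    if ("cluster" %in% tools) {
      emit(export_clusters(cl, config$member_cap), "cluster_members.csv")
    }
    if ("peaks" %in% tools || "cluster" %in% tools) {
      emit(cluster_peaks(cl, config$n), "cluster_peaks.csv")
    }
    if ("peak-track" %in% tools) {
      results$peak_track <- track_cluster_peaks(series, cl, config$n)
      emit(track_matrix(results$peak_track), "cluster_peak_track.csv")
    }
    if ("conservation" %in% tools) {
      members <- cluster_members(cl, config$cluster_rank)
      cm <- conservation_matrix(members, weighted = config$weighted)
      logo <- consensus_and_logo(cm)
      results$conservation <- cm
      results$logo <- logo
      emit(conservation_table(cm), "conservation_matrix.csv")
      emit(logo_table(logo), "consensus_logo.csv")
      emit(tibble::tibble(consensus = logo$consensus,
                          position = seq_along(logo$info_bits),
                          info_bits = logo$info_bits),
           "consensus_info.csv")
    }
  }

  results$manifest <- manifest
  invisible(results)
}
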