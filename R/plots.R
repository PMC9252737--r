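#' Plot abundance tracks across selection rounds
#'
#' Line plot of fractional abundance versus round for each tracked
#' sequence (or motif). The underlying numbers are available from
#' [track_matrix()], so figures are always reproducible from data.
#'
#' @param track Output of [track_sequences()], [track_cluster_peaks()]
#'   or `track_motif()$track`.
#' @return A ggplot object.
#' @export
plot_tracks <- function(track) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  stopifnot(all(c("sequence", "round", "fraction") %in% names(track)))
  lab <- function(s) paste0(substr(s, 1, 12),
                            ifelse(nchar(s) > 12, "...", ""))
  ggplot2::ggplot(track,
                  ggplot2::aes(x = .data$round, y = .data$fraction,
                               colour = lab(.data$sequence),
                               group = .data$sequence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(track$round)) +
    ggplot2::labs(x = "selection round", y = "fractional abundance",
                  colour = "sequence") +
    ggplot2::theme_minimal()
}

#' Plot a per-position conservation heatmap
#'
#' Heatmap of base frequency by position for a cluster, the standard
#' view for spotting conserved positions and motifs.
#'
#' @param matrix A [conservation_matrix()] result.
#' @return A ggplot object.
#' @export
plot_conservation <- function(matrix) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  tab <- conservation_table(matrix)
  ggplot2::ggplot(tab,
                  ggplot2::aes(x = .data$position, y = .data$base,
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "base", fill = "frequency") +
    ggplot2::theme_minimal()
}
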