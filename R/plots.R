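# ggplot2 views of the result objects. Each plot_*() works on plain tibbles
# too; autoplot() methods dispatch on the result classes.

#' Plot probe signal with segmentation overlaid
#'
#' Probe M values along the genomic coordinate with the called signal areas
#' drawn as horizontal bars at their pseudomedian level, faceted by strand.
#'
#' @param sas A `chipsad_sas` tibble (or any SAS tibble).
#' @param probes Optional probe tibble to underlay as points.
#' @param experiment,replicon Restrict the view to one track (defaults to the
#'   first present).
#' @return A ggplot object.
#' @export
plot_segmentation <- function(sas, probes = NULL, experiment = NULL,
                              replicon = NULL) {
  sas_tbl <- tibble::as_tibble(sas)
  experiment <- experiment %||% sas_tbl$experiment_id[1]
  replicon <- replicon %||% sas_tbl$replicon[1]
  sas_tbl <- dplyr::filter(sas_tbl, .data$experiment_id == experiment,
                           .data$replicon == replicon)
  p <- ggplot2::ggplot()
  if (!is.null(probes)) {
    probes <- dplyr::filter(tibble::as_tibble(probes),
                            .data$experiment_id == experiment,
                            .data$replicon == replicon)
    p <- p + ggplot2::geom_point(
      data = probes,
      ggplot2::aes(x = .data$start, y = .data$M),
      size = 0.4, alpha = 0.4, colour = "grey40")
  }
  p +
    ggplot2::geom_segment(
      data = sas_tbl,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$pseudomedian_M, yend = .data$pseudomedian_M),
      linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strand)) +
    ggplot2::labs(x = paste0("position on ", replicon, " (bp)"),
                  y = "M (log2 ratio)",
                  title = paste0("signal areas: ", experiment)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chipsad_sas <- function(object, probes = NULL, ...) {
  plot_segmentation(object, probes = probes, ...)
}

#' Plot a t profile with its change points
#'
#' @param profile Tibble from [t_profile()].
#' @param change_points Optional tibble from [detect_change_points()].
#' @param t_threshold Threshold drawn as horizontal guides.
#' @return A ggplot object.
#' @export
plot_t_profile <- function(profile, change_points = NULL, t_threshold = 3) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$x, y = .data$t)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(-t_threshold, t_threshold),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = "generalized t") +
    ggplot2::theme_minimal()
  if (!is.null(change_points) && nrow(change_points) > 0) {
    p <- p + ggplot2::geom_point(data = change_points,
                                 ggplot2::aes(x = .data$x, y = .data$t_value),
                                 colour = "firebrick", size = 2)
  }
  p
}

#' Heat-map style view of the experiment-by-transcript M matrix
#'
#' @param consensus A `chipsad_consensus` tibble.
#' @return A ggplot object (tile map; transcripts on the y axis).
#' @export
plot_consensus_matrix <- function(consensus) {
  long <- purrr::map2_dfr(consensus$consensus_id, consensus$per_experiment_M,
                          function(id, m) tibble::tibble(
                            consensus_id = id, experiment_id = names(m),
                            M = unname(m)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experiment_id,
                                     y = .data$consensus_id,
                                     fill = .data$M)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "M") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chipsad_consensus <- function(object, ...) {
  plot_consensus_matrix(object)
}

#' Bar chart of transcript classes
#'
#' @param annotation A `chipsad_annotation` tibble.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(annotation) {
  s <- class_summary(annotation)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$transcript_class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chipsad_annotation <- function(object, ...) {
  plot_class_summary(object)
}
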