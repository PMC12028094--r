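#' Plot per-position flexibility metrics of an analysed system
#'
#' Line profiles of N_eq and (when present) RMSF along the author-numbered
#' sequence, one facet per metric, optionally shading annotated regions.
#'
#' @param object a `pb_system` from [analyze_system()].
#' @param regions optional region tibble `name, start, end` to shade.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pb_system <- function(object, regions = NULL, ...) {
  flex <- tidy(object)
  metrics <- intersect(c("neq", "rmsf", "bfactor"), names(flex))
  long <- tidyr::pivot_longer(
    flex[c("position", metrics)],
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = metrics,
                        labels = toupper(metrics))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$value))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE, colour = "steelblue4") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      title = object$name, x = "residue position", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a system-vs-system comparison profile
#'
#' Per-position delta-PB and delta-N_eq (and delta-RMSF when available), with
#' the flagging threshold drawn on the delta-PB panel.
#'
#' @param object a `pb_comparison` from [compare_systems()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pb_comparison <- function(object, ...) {
  prof <- object$profile
  metrics <- intersect(c("delta_pb", "delta_neq", "delta_rmsf"), names(prof))
  long <- tidyr::pivot_longer(
    prof, cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  thr <- tibble(metric = "delta_pb", y = object$delta_pb_threshold)
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "firebrick4") +
    ggplot2::geom_hline(
      data = thr, ggplot2::aes(yintercept = .data$y),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      title = paste(object$systems, collapse = " vs "),
      x = "residue position", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' PB frequency map heat map
#'
#' The per-position Protein Block frequency matrix as a tile map (positions
#' along x, PBs `a`-`p` along y), the package's equivalent of a PB map /
#' logo frequency display.
#'
#' @param freqs a `pb_freq` tibble from [frequency_map()].
#' @return A ggplot object.
#' @export
plot_pb_map <- function(freqs) {
  long <- tidyr::pivot_longer(
    freqs, cols = dplyr::all_of(PB_LABELS),
    names_to = "pb", values_to = "frequency"
  )
  long$pb <- factor(long$pb, levels = rev(PB_LABELS))
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$pb, fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2c2c94", "#4575b4", "#ffffbf", "#f46d43", "#d73027"),
      limits = c(0, 1), na.value = "grey90"
    ) +
    ggplot2::labs(x = "residue position", y = "Protein Block") +
    ggplot2::theme_minimal()
}
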