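#' Plot the SLV graph with clonal complexes
#'
#' eBURST-style display: one point per ST (area proportional to isolate
#' frequency), SLV links as segments, complexes colored and founders
#' outlined.
#'
#' @param object A `clonal_complexes` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonal_complexes <- function(object, ...) {
  graph <- object$graph
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$st_id))
  )
  set.seed(1L)  # layout only; has no analytic consequence
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(
    st_id = graph$nodes$st_id,
    frequency = graph$nodes$frequency,
    x = xy[, 1], y = xy[, 2]
  ) |>
    dplyr::left_join(tidy(object), by = "st_id")
  edges <- graph$edges |>
    dplyr::left_join(nodes[, c("st_id", "x", "y")],
                     by = c("from" = "st_id")) |>
    dplyr::left_join(nodes[, c("st_id", "x", "y")],
                     by = c("to" = "st_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to),
      color = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$frequency,
                   color = .data$complex_id,
                   shape = .data$is_founder)
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$st_id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(color = "complex", shape = "founder", size = "isolates",
                  title = "Single-locus-variant graph of sequence types") +
    ggplot2::theme_void()
}

#' Plot a polymorphic-site matrix as a mosaic tile panel
#'
#' @param object A `polymorphic_matrix`.
#' @param ... Unused.
#' @return A ggplot with one tile per (sequence, variable site), colored by
#'   base; dots in the text layer mark identity with the reference.
#' @export
autoplot.polymorphic_matrix <- function(object, ...) {
  if (length(object$positions) == 0) {
    stop("no polymorphic sites to plot", call. = FALSE)
  }
  long <- object$rows |>
    dplyr::mutate(split = strsplit(.data$bases, "")) |>
    tidyr::unnest_longer("split", values_to = "base") |>
    dplyr::group_by(.data$isolate) |>
    dplyr::mutate(site = object$positions[dplyr::row_number()]) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$site), y = .data$isolate, fill = .data$base
  )) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2.5) +
    ggplot2::scale_fill_manual(values = c(
      A = "#66c2a5", C = "#fc8d62", G = "#8da0cb", T = "#e78ac3",
      `.` = "grey92", `-` = "grey75", N = "grey85"
    ), na.value = "grey95") +
    ggplot2::labs(
      x = "alignment position (variable sites only)", y = NULL,
      title = paste0("Polymorphic sites, ", object$locus,
                     " (ref = ", object$reference, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   legend.position = "none")
}

#' Plot the MaxChi statistic along the sequence
#'
#' @param object A `maxchi_scan`.
#' @param ... Unused.
#' @return A ggplot of the chi-square statistic at every candidate cut,
#'   with the called breakpoint marked.
#' @export
autoplot.maxchi_scan <- function(object, ...) {
  if (nrow(object$profile) == 0) {
    stop("no-call scan: nothing to plot", call. = FALSE)
  }
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = .data$statistic)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$call$position,
                        linetype = "dashed", color = "red") +
    ggplot2::labs(
      x = "alignment position", y = "2x2 chi-square",
      title = sprintf("MaxChi scan (max = %.2f, permutation p = %.3g)",
                      object$call$statistic, object$call$p_value)
    ) +
    ggplot2::theme_minimal()
}
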