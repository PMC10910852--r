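# ggplot2 views of the main result types -------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_point geom_col labs scale_x_log10 scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.spacer_null <- function(object, percentile = 95, ...) {
  thr <- threshold_from_null(object, percentile)
  ggplot(tidy(object), aes(x = .data$value)) +
    geom_histogram(bins = 50, fill = "grey60") +
    geom_vline(xintercept = thr, linetype = "dashed", colour = "firebrick") +
    labs(x = paste("null", object$index),
         y = "pair count",
         title = sprintf("permutation null (%d replicates), %gth percentile = %.3g",
                         object$n_replicates, percentile, thr)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.module_partition <- function(object, ...) {
  sizes <- as_tibble(object) |>
    dplyr::count(.data$module, name = "size")
  ggplot(sizes, aes(x = factor(.data$module), y = .data$size)) +
    geom_col(fill = "steelblue") +
    labs(x = "module", y = "isolates",
         title = sprintf("%d modules (%s)", nrow(sizes),
                         attr(object, "method"))) +
    theme_minimal()
}

#' Targets-vs-MAD scatter
#'
#' One point per targeted subject: number of unmasked hits against the
#' unscaled MAD of hit positions, with the region-calling cut-off drawn as a
#' dashed line. Prophage-bearing genomes sit at high hit counts and low MAD;
#' scattered-target genomes at high MAD.
#'
#' @param summary A `target_summary` tibble from [summarize_targets()].
#' @param min_hits Cut-off to draw (default 10).
#' @return A ggplot object.
#' @export
plot_target_summary <- function(summary, min_hits = 10) {
  dat <- filter(as_tibble(summary), !is.na(.data$mad))
  ggplot(dat, aes(x = .data$n_hits, y = .data$mad + 1)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = min_hits, linetype = "dashed") +
    scale_y_log10() +
    labs(x = "spacer targets", y = "MAD of target positions + 1",
         title = "target clustering per subject") +
    theme_minimal()
}

#' Spacer-sharing network layout
#'
#' Fruchterman-Reingold layout of the thresholded network, nodes coloured by
#' module.
#'
#' @param network Graph from [build_network()].
#' @param modules Optional `module_partition` for colouring.
#' @param seed Layout seed (default 1).
#' @return A ggplot object.
#' @export
plot_spacer_network <- function(network, modules = NULL, seed = 1) {
  xy <- with_seed_if(seed, igraph::layout_with_fr(network))
  nodes <- tibble(isolate_id = igraph::V(network)$name,
                  x = xy[, 1], y = xy[, 2])
  if (!is.null(modules)) {
    nodes <- left_join(nodes, as_tibble(modules), by = "isolate_id")
  } else {
    nodes$module <- 1L
  }
  el <- igraph::as_edgelist(network)
  edges <- tibble(
    x = nodes$x[match(el[, 1], nodes$isolate_id)],
    y = nodes$y[match(el[, 1], nodes$isolate_id)],
    xend = nodes$x[match(el[, 2], nodes$isolate_id)],
    yend = nodes$y[match(el[, 2], nodes$isolate_id)]
  )
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          aes(x = .data$x, y = .data$y,
                              xend = .data$xend, yend = .data$yend),
                          colour = "grey75", linewidth = 0.3) +
    geom_point(aes(colour = factor(.data$module)), size = 2) +
    labs(colour = "module", x = NULL, y = NULL) +
    ggplot2::theme_void()
}
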