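#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annotation set into its cluster/label table
#'
#' One row per cluster: id, label, node count and collapsed flag — the
#' table the pipeline writes as its TSV report.
#'
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return A tibble with columns `cluster`, `label`, `nodes`,
#'   `collapsed`.
#' @export
tidy.annotation_set <- function(x, ...) {
  tibble::tibble(
    cluster = x$clusters$cluster,
    label = x$clusters$label,
    nodes = lengths(x$clusters$members),
    collapsed = x$clusters$collapsed
  )
}

#' One-row summary of an annotation set
#'
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return A one-row tibble: name, cluster count, clustered-node count,
#'   label algorithm, max words, size bonus, and normalization factor.
#' @export
glance.annotation_set <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_clusters = nrow(x$clusters),
    n_nodes = length(unlist(x$clusters$members)),
    algorithm = x$label_options$algorithm,
    max_words = x$label_options$max_words,
    size_bonus = x$label_options$size_bonus,
    normalization = x$cloud_options$normalization
  )
}

#' Plot a network with cluster shapes and labels
#'
#' A ggplot2 rendering mirroring the SVG layer order: shapes under
#' edges, nodes on top, labels above the shapes. Intended for quick
#' inspection; [render_svg()] is the production renderer.
#'
#' @param object An `annotation_set` (or a `netan_network` for a plain
#'   drawing).
#' @param net The network the set annotates (annotation-set method
#'   only).
#' @param display A [display_options()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annotation_set <- function(object, net, display = display_options(),
                                    ...) {
  p <- autoplot.netan_network(net)
  drawable <- object$clusters[!object$clusters$collapsed, ]
  if (!nrow(drawable)) return(p)
  geoms <- lapply(seq_len(nrow(drawable)), function(i) {
    cluster_geometry(net, drawable[i, ], display)
  })
  boxes <- dplyr::bind_rows(lapply(geoms, function(g) {
    tibble::tibble(xmin = g$shape$x, xmax = g$shape$x + g$shape$w,
                   ymin = g$shape$y, ymax = g$shape$y + g$shape$h,
                   label = g$label$text,
                   lx = g$label$x, ly = g$label$y)
  }))
  boxes$fill <- cluster_palette()[(seq_len(nrow(boxes)) - 1) %% 8 + 1]
  if (display$shapes_visible) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = boxes$fill, alpha = display$fill_opacity,
      color = boxes$fill, linewidth = 0.4, inherit.aes = FALSE
    )
  }
  if (display$labels_visible) {
    p <- p + ggplot2::geom_text(
      data = boxes[nzchar(boxes$label), ],
      ggplot2::aes(x = .data$lx, y = .data$ly, label = .data$label),
      vjust = 1, size = display$base_font / 3, inherit.aes = FALSE
    )
  }
  p
}

#' @rdname autoplot.annotation_set
#' @export
autoplot.netan_network <- function(object, ...) {
  net <- object
  nodes <- net$nodes
  if (!all(has_positions(net, nodes$id))) net <- layout_network(net)
  nodes <- net$nodes
  e <- net$edges
  seg <- tibble::tibble(
    x = nodes$x[match(e$from, nodes$id)],
    y = nodes$y[match(e$from, nodes$id)],
    xend = nodes$x[match(e$to, nodes$id)],
    yend = nodes$y[match(e$to, nodes$id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
      color = "#1f78b4", size = 2
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a word cloud's sizes as a bar chart
#'
#' Words on the y axis ordered by font size, colored by adjacency
#' group — a quick textual view of what the label selectors see.
#'
#' @param object A `word_cloud` tibble from [build_cloud()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.word_cloud <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$size)
  d$word <- factor(d$word, levels = d$word)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$word,
                                  fill = factor(.data$group))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "font size", y = NULL, fill = "adjacency\ngroup") +
    ggplot2::theme_minimal()
}
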