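# small qualitative palette cycled by cluster index
cluster_palette <- function() {
  c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3",
    "#a6d854", "#ffd92f", "#e5c494", "#b3b3b3")
}

#' Render a network with its annotations as SVG
#'
#' Layers are stacked bottom to top: cluster shapes, edges, nodes,
#' cluster labels, so shapes sit beneath the graph and labels above it.
#' Collapsed clusters appear as their single group node, drawn larger
#' and labeled with the cluster label as its node name. Shape and label
#' layers honor the visibility toggles in [display_options()]; with no
#' annotation set, a plain network drawing is produced. The output is
#' well-formed SVG 1.1.
#'
#' @param net A `netan_network` whose nodes all carry `x`/`y`.
#' @param set An `annotation_set` or `NULL`.
#' @param display A [display_options()] object.
#' @param path Optional output path; when given the SVG is written there.
#' @param node_radius,edge_stroke Node radius and edge stroke width (px).
#' @return An `xml2` document (invisibly when `path` is given).
#' @export
render_svg <- function(net, set = NULL, display = display_options(),
                       path = NULL, node_radius = 8, edge_stroke = 1) {
  nodes <- net$nodes
  if (nrow(nodes)) {
    ok <- has_positions(net, nodes$id)
    if (!all(ok)) {
      stop("node(s) without coordinates: ",
           paste(nodes$id[!ok], collapse = ", "), call. = FALSE)
    }
  }

  geoms <- list()
  if (!is.null(set)) {
    drawable <- set$clusters[!set$clusters$collapsed, ]
    geoms <- lapply(seq_len(nrow(drawable)), function(i) {
      cluster_geometry(net, drawable[i, ], display)
    })
  }

  xs <- c(nodes$x, unlist(lapply(geoms, function(g) c(g$shape$x, g$shape$x + g$shape$w))))
  ys <- c(nodes$y, unlist(lapply(geoms, function(g) c(g$shape$y - 20, g$shape$y + g$shape$h))))
  if (!length(xs)) { xs <- c(0, 1); ys <- c(0, 1) }
  m <- 40
  vb <- c(min(xs) - m, min(ys) - m, diff(range(xs)) + 2 * m, diff(range(ys)) + 2 * m)

  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    viewBox = paste(fmt(vb), collapse = " "),
    width = fmt(vb[3]), height = fmt(vb[4])
  )

  pal <- cluster_palette()
  shapes_g <- xml2::xml_add_child(doc, "g", class = "cluster-shapes")
  labels <- list()
  if (length(geoms) && (display$shapes_visible || display$labels_visible)) {
    for (i in seq_along(geoms)) {
      g <- geoms[[i]]
      col <- pal[(i - 1) %% length(pal) + 1]
      if (display$shapes_visible) {
        if (g$shape$kind == "rectangle") {
          xml2::xml_add_child(shapes_g, "rect",
            x = fmt(g$shape$x), y = fmt(g$shape$y),
            width = fmt(g$shape$w), height = fmt(g$shape$h),
            fill = col, `fill-opacity` = fmt(display$fill_opacity),
            stroke = col, `stroke-width` = fmt(display$border_width))
        } else {
          # ellipse circumscribing the padded box so members stay inside
          s <- sqrt(2)
          xml2::xml_add_child(shapes_g, "ellipse",
            cx = fmt(g$shape$x + g$shape$w / 2),
            cy = fmt(g$shape$y + g$shape$h / 2),
            rx = fmt(g$shape$w / 2 * s), ry = fmt(g$shape$h / 2 * s),
            fill = col, `fill-opacity` = fmt(display$fill_opacity),
            stroke = col, `stroke-width` = fmt(display$border_width))
        }
      }
      if (display$labels_visible && nzchar(g$label$text)) {
        labels <- c(labels, list(g$label))
      }
    }
  }

  edges_g <- xml2::xml_add_child(doc, "g", class = "edges")
  e <- net$edges
  if (nrow(e)) {
    fi <- match(e$from, nodes$id)
    ti <- match(e$to, nodes$id)
    for (k in seq_len(nrow(e))) {
      xml2::xml_add_child(edges_g, "line",
        x1 = fmt(nodes$x[fi[k]]), y1 = fmt(nodes$y[fi[k]]),
        x2 = fmt(nodes$x[ti[k]]), y2 = fmt(nodes$y[ti[k]]),
        stroke = "#999999", `stroke-width` = fmt(edge_stroke))
    }
  }

  nodes_g <- xml2::xml_add_child(doc, "g", class = "nodes")
  is_group <- if ("is_group" %in% names(nodes)) nodes$is_group %in% TRUE
              else rep(FALSE, nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    r <- if (is_group[k]) node_radius * 1.8 else node_radius
    xml2::xml_add_child(nodes_g, "circle",
      cx = fmt(nodes$x[k]), cy = fmt(nodes$y[k]), r = fmt(r),
      fill = if (is_group[k]) "#4d4d4d" else "#1f78b4",
      stroke = "#ffffff", `stroke-width` = "1")
    if (is_group[k] && "name" %in% names(nodes) && !is.na(nodes$name[k])) {
      txt <- xml2::xml_add_child(nodes_g, "text",
        x = fmt(nodes$x[k]), y = fmt(nodes$y[k] - r - 3),
        `text-anchor` = "middle",
        `font-size` = fmt(display$base_font), `font-family` = "sans-serif")
      xml2::xml_set_text(txt, nodes$name[k])
    }
  }

  labels_g <- xml2::xml_add_child(doc, "g", class = "cluster-labels")
  for (lb in labels) {
    txt <- xml2::xml_add_child(labels_g, "text",
      x = fmt(lb$x), y = fmt(lb$y), `text-anchor` = "middle",
      `font-size` = fmt(lb$font_size), `font-family` = "sans-serif")
    xml2::xml_set_text(txt, lb$text)
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

fmt <- function(x) sprintf("%.6g", x)
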