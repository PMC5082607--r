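#' Display options for shape and label annotations
#'
#' @param shape `"ellipse"` (default) or `"rectangle"`.
#' @param border_width Shape border width in px (>= 0).
#' @param fill_opacity Shape fill opacity in \[0, 1\].
#' @param shapes_visible,labels_visible Layer visibility toggles.
#' @param base_font Label font size in pt (> 0).
#' @param font_scaling When `TRUE`, a cluster of n nodes gets label font
#'   `base_font * (1 + log10(n))`, so large clusters read larger without
#'   growing linearly.
#' @return A list of class `display_options`.
#' @export
display_options <- function(shape = c("ellipse", "rectangle"),
                            border_width = 1,
                            fill_opacity = 0.2,
                            shapes_visible = TRUE,
                            labels_visible = TRUE,
                            base_font = 12,
                            font_scaling = TRUE) {
  shape <- match.arg(shape)
  if (fill_opacity < 0 || fill_opacity > 1) stop("`fill_opacity` must lie in [0, 1]", call. = FALSE)
  if (border_width < 0) stop("`border_width` must be >= 0", call. = FALSE)
  if (base_font <= 0) stop("`base_font` must be positive", call. = FALSE)
  structure(
    list(shape = shape, border_width = border_width,
         fill_opacity = fill_opacity, shapes_visible = isTRUE(shapes_visible),
         labels_visible = isTRUE(labels_visible), base_font = base_font,
         font_scaling = isTRUE(font_scaling)),
    class = "display_options"
  )
}

new_annotation_set <- function(name, clusters, cloud_opts, label_opts, source) {
  structure(
    list(name = name, clusters = clusters, cloud_options = cloud_opts,
         label_options = label_opts, source = source),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set '%s': %d clusters (%s, max %d words)>\n",
              x$name, nrow(x$clusters), x$label_options$algorithm,
              x$label_options$max_words))
  print(tidy(x))
  invisible(x)
}

compute_cluster_label <- function(net, members, cloud_opts, label_opts) {
  cloud <- build_cloud(net, members, cloud_opts)
  label_from_cloud(cloud, label_opts)
}

#' Create an annotation set from a partition
#'
#' Builds one labeled cluster per partition cluster: the cluster's word
#' cloud is computed from the selected attributes and condensed to a
#' label with the selected algorithm. Identical inputs always produce
#' identical labels. A network may carry any number of annotation sets
#' (register them in an [annotation_session()]); at most one is active
#' at a time.
#'
#' @param net A `netan_network`.
#' @param partition A partition tibble (see [partition]); validated
#'   against `net`.
#' @param cloud_opts A [cloud_options()] object.
#' @param label_opts A [label_options()] object.
#' @param name Set name (unique per session).
#' @param source Free-form descriptor of how the clusters were made.
#' @return An `annotation_set`: name, options, and a `clusters` tibble
#'   with columns `cluster`, `members` (list), `label`, `collapsed`.
#' @export
create_annotation_set <- function(net, partition, cloud_opts,
                                  label_opts = label_options(),
                                  name = "Annotation Set",
                                  source = "partition") {
  validate_partition(net, partition)
  mem <- partition_members(partition)
  if (nrow(mem)) {
    mem <- mem |>
      dplyr::mutate(size = lengths(.data$members),
                    first = purrr::map_chr(.data$members, 1)) |>
      dplyr::arrange(dplyr::desc(.data$size), .data$first)
    labels <- purrr::map_chr(mem$members, compute_cluster_label,
                             net = net, cloud_opts = cloud_opts,
                             label_opts = label_opts)
    clusters <- tibble::tibble(cluster = mem$cluster, members = mem$members,
                               label = labels, collapsed = FALSE)
  } else {
    clusters <- tibble::tibble(cluster = character(), members = list(),
                               label = character(), collapsed = logical())
  }
  new_annotation_set(name, clusters, cloud_opts, label_opts, source)
}

check_disjoint <- function(set) {
  all_members <- unlist(set$clusters$members)
  if (anyDuplicated(all_members)) {
    stop("cluster member sets overlap", call. = FALSE)
  }
  if (any(lengths(set$clusters$members) == 0 & !set$clusters$collapsed)) {
    stop("empty uncollapsed cluster", call. = FALSE)
  }
  invisible(set)
}

cluster_row <- function(set, cluster_id) {
  i <- match(cluster_id, set$clusters$cluster)
  if (is.na(i)) stop("unknown cluster id: ", cluster_id, call. = FALSE)
  i
}

#' Merge clusters of an annotation set into one
#'
#' Member sets are unioned, the label is recomputed from the merged
#' member set with the set's own options, and the originals are removed.
#'
#' @param set An `annotation_set`.
#' @param net The network the set annotates.
#' @param cluster_ids At least two distinct cluster ids, none collapsed.
#' @return The modified set; the merged cluster keeps the first id.
#' @export
merge_clusters <- function(set, net, cluster_ids) {
  cluster_ids <- as.character(cluster_ids)
  if (length(cluster_ids) < 2 || anyDuplicated(cluster_ids)) {
    stop("need at least two distinct cluster ids", call. = FALSE)
  }
  rows <- vapply(cluster_ids, cluster_row, 0L, set = set)
  if (any(set$clusters$collapsed[rows])) {
    stop("cannot merge collapsed clusters; expand first", call. = FALSE)
  }
  members <- sort(unique(unlist(set$clusters$members[rows])))
  label <- compute_cluster_label(net, members, set$cloud_options, set$label_options)
  keep <- set$clusters[-rows[-1], ]
  i <- match(cluster_ids[1], keep$cluster)
  keep$members[[i]] <- members
  keep$label[i] <- label
  set$clusters <- keep
  check_disjoint(set)
  set
}

next_cluster_id <- function(set) {
  nums <- suppressWarnings(as.integer(set$clusters$cluster))
  as.character(max(c(0L, nums), na.rm = TRUE) + 1L)
}

#' Create a new cluster from selected nodes
#'
#' Selected nodes already belonging to another cluster are moved out of
#' it; clusters emptied by the move are dropped, preserving
#' disjointness.
#'
#' @param set An `annotation_set`.
#' @param net The network the set annotates.
#' @param node_ids Non-empty character vector of node ids.
#' @return The modified set with the new cluster appended (fresh id,
#'   computed label).
#' @export
create_cluster_from_selection <- function(set, net, node_ids) {
  node_ids <- unique(as.character(node_ids))
  if (!length(node_ids)) stop("empty selection", call. = FALSE)
  bad <- setdiff(node_ids, net$nodes$id)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(set$clusters$collapsed)) {
    stop("expand collapsed clusters before editing", call. = FALSE)
  }
  cl <- set$clusters
  cl$members <- lapply(cl$members, setdiff, y = node_ids)
  cl <- cl[lengths(cl$members) > 0, ]
  members <- sort(node_ids)
  label <- compute_cluster_label(net, members, set$cloud_options, set$label_options)
  set$clusters <- dplyr::bind_rows(
    cl,
    tibble::tibble(cluster = next_cluster_id(set), members = list(members),
                   label = label, collapsed = FALSE)
  )
  check_disjoint(set)
  set
}

#' Set or recompute a cluster's label
#'
#' @param set An `annotation_set`.
#' @param net The network the set annotates (used when recomputing).
#' @param cluster_id Cluster id.
#' @param label Manual label text (verbatim; may be empty, in which case
#'   the label annotation is hidden when rendering). Ignored when
#'   `recompute = TRUE`.
#' @param recompute Recompute the label from the set's current options.
#' @return The modified set.
#' @export
relabel <- function(set, net, cluster_id, label = NULL, recompute = FALSE) {
  i <- cluster_row(set, cluster_id)
  if (isTRUE(recompute)) {
    set$clusters$label[i] <- compute_cluster_label(
      net, set$clusters$members[[i]], set$cloud_options, set$label_options)
  } else {
    if (is.null(label) || !is.character(label)) {
      stop("supply `label` or set `recompute = TRUE`", call. = FALSE)
    }
    set$clusters$label[i] <- label
  }
  set
}

#' Shape and label geometry for one cluster
#'
#' The shape is the axis-aligned bounding box of the member positions
#' expanded by `padding` on every side (an ellipse circumscribes the
#' padded box, so members always fall inside either shape kind). The
#' label is anchored horizontally centered just above the box top; its
#' font is `base_font`, multiplied by `1 + log10(n_members)` when font
#' scaling is on. Geometry always reflects the network's current
#' coordinates, so moving nodes and recomputing repositions the
#' annotation.
#'
#' @param net A `netan_network` whose member nodes all carry `x`/`y`.
#' @param cluster A one-row slice of a set's `clusters` tibble, or a
#'   list with elements `members` and `label`.
#' @param display A [display_options()] object.
#' @param padding Box padding in layout units (default 10).
#' @return A list with elements `shape` (x, y, w, h, kind) and `label`
#'   (text, x, y anchor, font_size).
#' @export
cluster_geometry <- function(net, cluster, display = display_options(),
                             padding = 10) {
  members <- if (is.data.frame(cluster)) cluster$members[[1]] else cluster$members
  label <- if (is.data.frame(cluster)) cluster$label[[1]] else cluster$label
  if (!all(has_positions(net, members))) {
    missing <- members[!has_positions(net, members)]
    stop("member(s) without coordinates: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i <- match(members, net$nodes$id)
  xs <- net$nodes$x[i]
  ys <- net$nodes$y[i]
  x0 <- min(xs) - padding
  y0 <- min(ys) - padding
  w <- diff(range(xs)) + 2 * padding
  h <- diff(range(ys)) + 2 * padding
  font <- display$base_font *
    if (display$font_scaling) 1 + log10(length(members)) else 1
  list(
    shape = list(x = x0, y = y0, w = w, h = h, kind = display$shape),
    label = list(text = label, x = x0 + w / 2, y = y0 - 2, font_size = font)
  )
}

#' Sessions: a network with its annotation sets
#'
#' A session owns the network, a named list of annotation sets, the
#' active-set marker, and the collapse records of the active set. All
#' session functions are pure: they return the modified session.
#'
#' @param net A `netan_network`.
#' @return A list of class `annotation_session`.
#' @export
annotation_session <- function(net) {
  structure(
    list(network = net, sets = list(), active = NULL, records = list()),
    class = "annotation_session"
  )
}

#' @export
print.annotation_session <- function(x, ...) {
  cat(sprintf("<session: %d nodes, %d sets, active = %s>\n",
              nrow(x$network$nodes), length(x$sets),
              x$active %||% "<none>"))
  invisible(x)
}

#' Register an annotation set in a session
#' @param session An [annotation_session()].
#' @param set An `annotation_set`; its name must be new to the session.
#' @param activate Make it the active set (default when it is the first).
#' @return The modified session.
#' @export
session_add <- function(session, set, activate = length(session$sets) == 0) {
  force(activate)
  if (set$name %in% names(session$sets)) {
    stop("an annotation set named '", set$name, "' already exists", call. = FALSE)
  }
  session$sets[[set$name]] <- set
  if (activate) session$active <- set$name
  session
}

#' Switch the active annotation set
#'
#' Collapsed clusters of the currently active set must be expanded
#' first, because the grouped nodes may belong to different clusters in
#' the other set.
#'
#' @param session An [annotation_session()].
#' @param name Name of a registered set, or `NULL` to clear (renders
#'   then show no annotations).
#' @return The modified session.
#' @export
set_active <- function(session, name) {
  if (!is.null(session$active)) {
    cur <- session$sets[[session$active]]
    if (any(cur$clusters$collapsed)) {
      stop("collapsed clusters present in '", session$active,
           "'; expand all clusters before switching annotation sets",
           call. = FALSE)
    }
  }
  if (!is.null(name) && !name %in% names(session$sets)) {
    stop("no annotation set named '", name, "'", call. = FALSE)
  }
  session$active <- name
  session
}

active_set <- function(session) {
  if (is.null(session$active)) NULL else session$sets[[session$active]]
}
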