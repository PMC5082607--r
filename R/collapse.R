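#' Collapse a cluster into a single labeled group node
#'
#' The member nodes and every edge incident to them are removed and
#' replaced by one group node (id `"group:<cluster id>"`, `name`
#' attribute set to the cluster label, positioned at the member
#' centroid). For each external node adjacent to at least one member,
#' exactly one meta-edge is created from the group node, carrying a
#' `count` attribute equal to the number of underlying boundary edges
#' and `is_meta = TRUE`. Everything removed is stored in the returned
#' record so [expand_cluster()] can restore the pre-collapse network
#' exactly. Meta-edges carry no aggregated weight: only connectivity
#' and the boundary-edge count are summarized.
#'
#' Collapsing several clusters sequentially makes earlier group nodes
#' external to later collapses, so two adjacent collapsed clusters end
#' up joined by a single meta-edge between their group nodes. Expansion
#' must then happen in reverse order (see [expand_all()]).
#'
#' @param net A `netan_network`.
#' @param members Character vector of member node ids.
#' @param cluster_id Cluster id (used to derive the group-node id).
#' @param label Cluster label; becomes the group node's `name`.
#' @return A list with elements `network` (the collapsed network) and
#'   `record` (a collapse record).
#' @export
collapse_cluster <- function(net, members, cluster_id, label = "") {
  members <- as.character(members)
  group_id <- paste0("group:", cluster_id)
  if (group_id %in% net$nodes$id) {
    stop("cluster '", cluster_id, "' is already collapsed", call. = FALSE)
  }
  bad <- setdiff(members, net$nodes$id)
  if (length(bad)) stop("member(s) not in network: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  in_set <- net$nodes$id %in% members
  removed_nodes <- net$nodes[in_set, ]
  e <- net$edges
  from_in <- e$from %in% members
  to_in <- e$to %in% members
  incident <- from_in | to_in
  removed_edges <- e[incident, ]
  boundary <- e[xor(from_in, to_in), ]
  external <- ifelse(boundary$from %in% members, boundary$to, boundary$from)

  centroid <- if (all(has_positions(net, members))) {
    i <- match(members, net$nodes$id)
    c(mean(net$nodes$x[i]), mean(net$nodes$y[i]))
  } else c(NA_real_, NA_real_)

  nodes <- net$nodes[!in_set, ]
  group_row <- tibble::tibble(id = group_id)
  if ("x" %in% names(nodes) || !is.na(centroid[1])) {
    group_row$x <- centroid[1]
    group_row$y <- centroid[2]
  }
  group_row$name <- label
  group_row$is_group <- TRUE
  if (!"is_group" %in% names(nodes) && nrow(nodes)) nodes$is_group <- FALSE
  nodes <- dplyr::bind_rows(nodes, group_row)

  meta <- if (length(external)) {
    cnt <- table(external)
    tibble::tibble(from = group_id, to = names(cnt),
                   count = as.integer(cnt), is_meta = TRUE)
  } else {
    tibble::tibble(from = character(), to = character(),
                   count = integer(), is_meta = logical())
  }
  edges <- dplyr::bind_rows(e[!incident, ], meta)

  net2 <- net
  net2$nodes <- nodes
  net2$edges <- edges
  validate_network(net2)
  record <- list(
    group_id = group_id, cluster_id = as.character(cluster_id), label = label,
    nodes = removed_nodes, edges = removed_edges, meta_edges = meta,
    node_cols = names(net$nodes), edge_cols = names(net$edges)
  )
  list(network = net2, record = record)
}

drop_allna_extras <- function(tbl, keep_cols) {
  extras <- setdiff(names(tbl), keep_cols)
  for (col in extras) {
    v <- tbl[[col]]
    if (all(is.na(v) | (is.logical(v) & !v %in% TRUE))) tbl[[col]] <- NULL
  }
  tbl
}

#' Expand a collapsed cluster from its record
#'
#' Removes the group node together with every edge incident to it (its
#' meta-edges) and restores the stored member nodes, attributes,
#' positions and edges, reproducing the pre-collapse node set, edge
#' multiset, and attributes.
#'
#' @param net A collapsed `netan_network`.
#' @param record The record returned by [collapse_cluster()].
#' @return The restored network.
#' @export
expand_cluster <- function(net, record) {
  gid <- record$group_id
  if (!gid %in% net$nodes$id) {
    stop("group node '", gid, "' is missing; cluster is not collapsed",
         call. = FALSE)
  }
  nodes <- net$nodes[net$nodes$id != gid, ]
  edges <- net$edges[net$edges$from != gid & net$edges$to != gid, ]
  missing_ends <- setdiff(c(record$edges$from, record$edges$to),
                          c(nodes$id, record$nodes$id))
  if (length(missing_ends)) {
    stop("cannot restore edges: endpoint(s) still collapsed or deleted: ",
         paste(missing_ends, collapse = ", "),
         " (expand clusters in reverse order of collapse)", call. = FALSE)
  }
  nodes <- dplyr::bind_rows(nodes, record$nodes)
  edges <- dplyr::bind_rows(edges, record$edges)
  net$nodes <- drop_allna_extras(nodes, record$node_cols)
  net$edges <- drop_allna_extras(edges, record$edge_cols)
  validate_network(net)
  net
}

session_active_or_stop <- function(session) {
  if (is.null(session$active)) stop("no active annotation set", call. = FALSE)
  session$sets[[session$active]]
}

#' Collapse or expand clusters of the active annotation set
#'
#' `session_collapse()` collapses one cluster of the active set;
#' `session_expand()` restores it. `collapse_all()` collapses every
#' uncollapsed cluster (unclustered nodes are untouched and keep their
#' original attributes); `expand_all()` restores them in reverse
#' collapse order, returning the original network exactly. Shape and
#' label annotations are no longer drawn for collapsed clusters.
#'
#' @param session An [annotation_session()] with an active set.
#' @param cluster_id Cluster id within the active set.
#' @return The modified session.
#' @export
session_collapse <- function(session, cluster_id) {
  set <- session_active_or_stop(session)
  i <- cluster_row(set, cluster_id)
  if (set$clusters$collapsed[i]) {
    stop("cluster '", cluster_id, "' is already collapsed", call. = FALSE)
  }
  res <- collapse_cluster(session$network, set$clusters$members[[i]],
                          cluster_id, set$clusters$label[i])
  session$network <- res$network
  set$clusters$collapsed[i] <- TRUE
  session$sets[[session$active]] <- set
  session$records <- c(session$records, list(res$record))
  session
}

#' @rdname session_collapse
#' @export
session_expand <- function(session, cluster_id) {
  set <- session_active_or_stop(session)
  i <- cluster_row(set, cluster_id)
  if (!set$clusters$collapsed[i]) {
    stop("cluster '", cluster_id, "' is not collapsed", call. = FALSE)
  }
  ri <- which(vapply(session$records, function(r) r$cluster_id, "") ==
                as.character(cluster_id))
  if (!length(ri)) stop("no collapse record for cluster '", cluster_id, "'",
                        call. = FALSE)
  ri <- ri[length(ri)]
  session$network <- expand_cluster(session$network, session$records[[ri]])
  session$records <- session$records[-ri]
  set$clusters$collapsed[i] <- FALSE
  session$sets[[session$active]] <- set
  session
}

#' @rdname session_collapse
#' @export
collapse_all <- function(session) {
  set <- session_active_or_stop(session)
  for (id in set$clusters$cluster[!set$clusters$collapsed]) {
    session <- session_collapse(session, id)
  }
  session
}

#' @rdname session_collapse
#' @export
expand_all <- function(session) {
  set <- session_active_or_stop(session)
  ids <- rev(vapply(session$records, function(r) r$cluster_id, ""))
  for (id in ids[ids %in% set$clusters$cluster[set$clusters$collapsed]]) {
    session <- session_expand(session, id)
  }
  session
}
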