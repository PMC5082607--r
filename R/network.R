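#' Construct a network from node and edge tables
#'
#' The package's network container is a pair of tibbles: a `nodes` table
#' with one row per node (column `id`, optional numeric `x`/`y` layout
#' coordinates, plus any number of text or numeric attribute columns) and
#' an `edges` table with one row per edge (columns `from`/`to`, optional
#' numeric `weight`, plus further edge attributes). Node ids are opaque,
#' non-empty, unique strings; numeric-looking ids are never coerced.
#' Edges are stored as given (a `directed` flag records the input
#' convention) but all clustering, adjacency, and collapse logic treats
#' the graph as undirected, and parallel edges are deduplicated for
#' adjacency queries while being preserved in storage.
#'
#' @param nodes A data frame with at least an `id` column, or a character
#'   vector of node ids.
#' @param edges A data frame with `from` and `to` columns (may be `NULL`
#'   or empty for an edgeless network).
#' @param directed Whether input edges carry a direction (stored for
#'   round-tripping only; ignored by all analyses).
#' @return An object of class `netan_network`: a list with elements
#'   `nodes` (tibble), `edges` (tibble), and `directed` (flag).
#' @examples
#' net <- make_network(
#'   nodes = tibble::tibble(id = c("a", "b", "c"), desc = "dna repair"),
#'   edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
#' )
#' network_nodes(net)
#' @export
make_network <- function(nodes, edges = NULL, directed = FALSE) {
  if (is.character(nodes)) nodes <- tibble::tibble(id = nodes)
  nodes <- tibble::as_tibble(nodes)
  if (!"id" %in% names(nodes)) {
    stop("`nodes` must have an `id` column", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  if (is.null(edges) || ncol(as.data.frame(edges)) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have `from` and `to` columns", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  net <- structure(
    list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
    class = "netan_network"
  )
  validate_network(net)
  net
}

#' @export
print.netan_network <- function(x, ...) {
  attrs <- setdiff(names(x$nodes), c("id", "x", "y"))
  cat(sprintf(
    "<network: %d nodes, %d edges%s>\n",
    nrow(x$nodes), nrow(x$edges),
    if (length(attrs)) paste0("; node attrs: ", paste(attrs, collapse = ", ")) else ""
  ))
  invisible(x)
}

validate_network <- function(net) {
  ids <- net$nodes$id
  if (anyDuplicated(ids)) {
    stop("duplicate node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(ids) | ids == "")) stop("node ids must be non-empty", call. = FALSE)
  bad <- setdiff(c(net$edges$from, net$edges$to), ids)
  if (length(bad)) {
    stop("edge endpoints not in node set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("x", "y"), names(net$nodes))) {
    v <- net$nodes[[col]]
    if (!is.numeric(v) || any(!is.finite(v) & !is.na(v))) {
      stop("positions must be finite numbers (column `", col, "`)", call. = FALSE)
    }
  }
  invisible(net)
}

#' Node and edge tables of a network
#' @param net A `netan_network`.
#' @return A tibble.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname network_nodes
#' @export
network_edges <- function(net) net$edges

#' Nodes adjacent to a node (undirected, parallel edges deduplicated)
#' @param net A `netan_network`.
#' @param id A node id.
#' @return Character vector of neighbour ids (no self-loops).
#' @export
adjacent_nodes <- function(net, id) {
  e <- net$edges
  nb <- c(e$to[e$from == id], e$from[e$to == id])
  sort(unique(setdiff(nb, id)))
}

#' Does the network have coordinates for the given nodes?
#' @noRd
has_positions <- function(net, ids = net$nodes$id) {
  if (!all(c("x", "y") %in% names(net$nodes))) return(rep(FALSE, length(ids)))
  i <- match(ids, net$nodes$id)
  !is.na(net$nodes$x[i]) & !is.na(net$nodes$y[i])
}

#' Read a network from GraphML or a tab-separated edge list
#'
#' GraphML is read via igraph and carries node/edge attributes and any
#' `x`/`y` coordinate keys. The edge-list dialect is
#' `source<TAB>target[<TAB>weight]` with one optional header line.
#'
#' @param path Path to the file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return A [make_network()] object.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    graphml = read_network_graphml(path),
    edgelist = read_network_edgelist(path)
  )
}

read_network_graphml <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) stop("failed to parse GraphML '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- igraph::vcount(g)
  vat <- igraph::vertex_attr(g)
  ids <- if (!is.null(vat$name)) as.character(vat$name)
         else if (!is.null(vat$id)) as.character(vat$id)
         else as.character(seq_len(n))
  # "name" carries our node ids; "id" is the GraphML XML node id igraph
  # surfaces as a vertex attribute — both are identity, not data
  nodes <- tibble::tibble(id = ids)
  for (a in setdiff(names(vat), c("name", "id"))) {
    nodes[[a]] <- vat[[a]]
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]])
  for (a in names(igraph::edge_attr(g))) edges[[a]] <- igraph::edge_attr(g, a)
  make_network(nodes, edges, directed = igraph::is_directed(g))
}

read_network_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(make_network(character()))
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2 &&
      tolower(first[[1]]) %in% c("source", "from") &&
      tolower(first[[2]]) %in% c("target", "to")) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(make_network(character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("malformed edge list '", path, "' at line ", which(nf < 2)[1],
         ": expected at least source<TAB>target", call. = FALSE)
  }
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)
  edges <- tibble::tibble(from = from, to = to)
  if (any(nf >= 3)) {
    w <- suppressWarnings(as.numeric(vapply(parts, function(p) {
      if (length(p) >= 3) p[[3]] else NA_character_
    }, "")))
    bad <- which(nf >= 3 & is.na(w))
    if (length(bad)) {
      stop("malformed edge list '", path, "' at line ", bad[1],
           ": non-numeric weight", call. = FALSE)
    }
    edges$weight <- w
  }
  ids <- unique(c(from, to))
  make_network(ids, edges)
}

#' Write a network to GraphML or a tab-separated edge list
#'
#' GraphML (via igraph) preserves nodes, edges, attributes and
#' coordinates so that [read_network()] round-trips the object; the
#' edge-list format keeps only edges and, when present, their `weight`
#' column.
#'
#' @inheritParams read_network
#' @param net A `netan_network`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "edgelist") {
    e <- net$edges
    cols <- c("from", "to", intersect("weight", names(e)))
    out <- do.call(paste, c(unname(as.list(e[cols])), sep = "\t"))
    writeLines(out, path)
    return(invisible(path))
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert between the package's network container and igraph
#' @param net A `netan_network`.
#' @return An igraph graph whose vertex `name` attribute carries node ids.
#' @export
as_igraph <- function(net) {
  nodes <- net$nodes
  names(nodes)[names(nodes) == "id"] <- "name"
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = net$directed,
    vertices = as.data.frame(nodes)
  )
}

#' Read a node attribute table
#'
#' Expects a TSV whose first column (conventionally named `id`) holds
#' node ids; remaining columns are text or numeric attributes.
#'
#' @param path Path to the TSV file.
#' @return A tibble with an `id` column.
#' @export
read_attribute_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!ncol(tbl)) stop("empty attribute table: ", path, call. = FALSE)
  names(tbl)[1] <- "id"
  tbl$id <- as.character(tbl$id)
  tbl
}

#' Merge an attribute table into a network's node table
#'
#' Table rows whose id matches no node are not silently dropped: their
#' ids are reported in a warning and attached to the result as the
#' `unmatched_ids` attribute. Attribute columns already present on the
#' network are overwritten for matched nodes.
#'
#' @param net A `netan_network`.
#' @param table A data frame keyed by an `id` column (see
#'   [read_attribute_table()]).
#' @return The network with merged node attributes.
#' @export
bind_attributes <- function(net, table) {
  table <- tibble::as_tibble(table)
  if (!nrow(table) || ncol(table) < 2) return(net)
  if (!"id" %in% names(table)) names(table)[1] <- "id"
  table$id <- as.character(table$id)
  if (anyDuplicated(table$id)) {
    stop("duplicate node-id rows in attribute table: ",
         paste(unique(table$id[duplicated(table$id)]), collapse = ", "),
         call. = FALSE)
  }
  unmatched <- setdiff(table$id, net$nodes$id)
  if (length(unmatched)) {
    warning(length(unmatched), " attribute row(s) match no node: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
    table <- table[table$id %in% net$nodes$id, , drop = FALSE]
  }
  nodes <- net$nodes
  for (col in setdiff(names(table), "id")) {
    i <- match(table$id, nodes$id)
    if (!col %in% names(nodes)) {
      nodes[[col]] <- if (is.numeric(table[[col]])) NA_real_ else NA_character_
    }
    nodes[[col]][i] <- table[[col]]
  }
  net$nodes <- nodes
  attr(net, "unmatched_ids") <- unmatched
  net
}
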