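#' Cluster partitions
#'
#' A partition is a tibble with columns `node` and `cluster` (character;
#' `NA` marks unclustered nodes). Clusters are pairwise disjoint by
#' construction, cover the node set together with the unclustered pool,
#' and are never empty.
#'
#' @name partition
NULL

new_partition <- function(node, cluster) {
  tbl <- tibble::tibble(node = as.character(node), cluster = as.character(cluster))
  class(tbl) <- c("netan_partition", class(tbl))
  tbl
}

#' Validate a partition against a network
#'
#' Checks the disjoint-cover invariant: every network node appears in
#' exactly one row, clusters are non-empty, and no foreign nodes appear.
#'
#' @param net A `netan_network`.
#' @param partition A partition tibble (columns `node`, `cluster`).
#' @return Invisibly, the partition.
#' @export
validate_partition <- function(net, partition) {
  if (anyDuplicated(partition$node)) {
    stop("partition assigns a node to more than one cluster", call. = FALSE)
  }
  if (!setequal(partition$node, net$nodes$id)) {
    stop("partition does not cover the network's node set", call. = FALSE)
  }
  sizes <- table(partition$cluster)
  if (any(sizes == 0)) stop("empty cluster in partition", call. = FALSE)
  invisible(partition)
}

#' Cluster nodes by a shared attribute value
#'
#' Nodes with the same value of `attr` form one cluster; nodes missing
#' the attribute (or with an empty value) are left unclustered.
#'
#' @param net A `netan_network`.
#' @param attr Name of a node attribute column.
#' @return A partition tibble (see [partition]).
#' @export
clusters_from_attribute <- function(net, attr) {
  if (!attr %in% names(net$nodes)) {
    stop("attribute `", attr, "` is present on no node", call. = FALSE)
  }
  v <- net$nodes[[attr]]
  v <- as.character(v)
  v[!is.na(v) & v == ""] <- NA_character_
  if (all(is.na(v))) {
    stop("attribute `", attr, "` is present on no node", call. = FALSE)
  }
  new_partition(net$nodes$id, v)
}

#' Build a partition from explicit cluster assignments
#'
#' @param net A `netan_network`.
#' @param assignments Named vector or list: node id -> cluster id. Ids
#'   are treated as opaque; the numeric id `1` and the string `"1"` name
#'   the same cluster only because both print as `"1"` — supply
#'   distinctly printed ids for distinct clusters.
#' @return A partition tibble covering all network nodes; unassigned
#'   nodes are unclustered.
#' @export
partition_from_ids <- function(net, assignments) {
  ids <- net$nodes$id
  cl <- rep(NA_character_, length(ids))
  if (length(assignments)) {
    keys <- names(assignments)
    if (is.null(keys)) stop("`assignments` must be named by node id", call. = FALSE)
    vals <- vapply(assignments, function(x) as.character(x), "")
    i <- match(keys, ids)
    cl[i[!is.na(i)]] <- vals[!is.na(i)]
  }
  new_partition(ids, cl)
}

#' Markov clustering (MCL) of a network
#'
#' Standard MCL on the undirected (deduplicated) adjacency structure:
#' self-loops of weight 1 are added, columns are normalized to a
#' transition matrix, and expansion (matrix squaring) alternates with
#' inflation (entrywise power `inflation` followed by column
#' renormalization) until successive matrices differ by less than
#' `tol` in max norm or `max_iter` iterations elapse. Entries below
#' `prune` are zeroed each iteration. Clusters are read off attractor
#' rows; overlapping attractor systems are merged, and any node
#' attracted to no attractor becomes its own singleton cluster.
#' Disconnected components are never merged, so the result always
#' refines the connected-components partition. The procedure is fully
#' deterministic.
#'
#' Cluster ids are consecutive integers (as strings) ordered by
#' descending cluster size, ties broken by smallest member id.
#'
#' @param net A `netan_network` with at least one node.
#' @param edge_weight_attr Name of a positive numeric edge attribute to
#'   weight the transition matrix, or `NULL` for unit weights. Weights
#'   of parallel edges are summed.
#' @param inflation Inflation exponent, must exceed 1. Default 2.
#' @param max_iter,tol,prune Iteration controls (see above).
#' @return A partition tibble with no unclustered nodes.
#' @export
mcl_clusters <- function(net, edge_weight_attr = NULL, inflation = 2,
                         max_iter = 100, tol = 1e-8, prune = 1e-6) {
  ids <- net$nodes$id
  n <- length(ids)
  if (n < 1) stop("network must have at least one node", call. = FALSE)
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("`inflation` must be > 1", call. = FALSE)
  }
  w <- if (is.null(edge_weight_attr)) {
    rep(1, nrow(net$edges))
  } else {
    if (!edge_weight_attr %in% names(net$edges)) {
      stop("edge weight attribute `", edge_weight_attr, "` not found", call. = FALSE)
    }
    as.numeric(net$edges[[edge_weight_attr]])
  }
  if (any(is.na(w) | w <= 0)) stop("edge weights must be positive", call. = FALSE)

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, ids)
    ti <- match(net$edges$to, ids)
    for (e in seq_along(fi)) {
      if (fi[e] == ti[e]) next  # self-loops added uniformly below
      A[fi[e], ti[e]] <- A[fi[e], ti[e]] + w[e]
      A[ti[e], fi[e]] <- A[ti[e], fi[e]] + w[e]
    }
  }
  diag(A) <- diag(A) + 1
  M <- sweep(A, 2, colSums(A), "/")
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }

  # attractor rows: nonzero diagonal; node j joins attractor i when M[i, j] > 0
  attractors <- which(diag(M) > 0)
  assign <- rep(NA_integer_, n)
  comp_of <- seq_along(attractors)  # union-find over attractor rows
  find <- function(i) { while (comp_of[i] != i) i <- comp_of[i]; i }
  for (j in seq_len(n)) {
    owners <- attractors[M[attractors, j, drop = TRUE] > 0]
    if (!length(owners)) next
    ks <- vapply(match(owners, attractors), find, 0L)
    root <- min(ks)
    for (k in ks) comp_of[k] <- root
    assign[j] <- root
  }
  assign <- vapply(seq_len(n), function(j) {
    if (is.na(assign[j])) NA_integer_ else find(assign[j])
  }, 0L)
  # singletons for unattracted nodes
  nxt <- max(c(0L, assign), na.rm = TRUE)
  for (j in which(is.na(assign))) {
    nxt <- nxt + 1L
    assign[j] <- nxt
  }

  relabel_partition(new_partition(ids, as.character(assign)))
}

#' Renumber cluster ids as "1", "2", ... by descending size,
#' ties by smallest member id.
#' @noRd
relabel_partition <- function(partition) {
  cl <- partition$cluster
  keep <- !is.na(cl)
  if (!any(keep)) return(partition)
  info <- tibble::tibble(cluster = cl[keep], node = partition$node[keep]) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(), first = min(.data$node), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first)
  map <- stats::setNames(as.character(seq_len(nrow(info))), info$cluster)
  partition$cluster[keep] <- unname(map[cl[keep]])
  partition
}

#' List the member nodes of each cluster in a partition
#' @param partition A partition tibble.
#' @return A tibble with columns `cluster` and `members` (list of
#'   character vectors), one row per cluster, unclustered nodes omitted.
#' @export
partition_members <- function(partition) {
  partition |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(members = list(sort(.data$node)), .groups = "drop")
}
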