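SESSION_FORMAT_VERSION <- 1L

# ---- typed column-wise (de)serialization of tibbles --------------------
# Plain row-oriented JSON loses column types on empty tables and NA-only
# columns; storing columns with an explicit type tag makes round-trips
# structural.

df_to_json <- function(df) {
  list(
    columns = lapply(stats::setNames(names(df), names(df)), function(cn) {
      v <- df[[cn]]
      vals <- lapply(seq_along(v), function(i) if (is.na(v[i])) NULL else v[i])
      list(type = class(v)[1], values = vals)
    }),
    nrow = nrow(df)
  )
}

df_from_json <- function(x) {
  cols <- lapply(x$columns, function(col) {
    tmpl <- restore_mode(col$type)
    vapply(col$values, function(e) {
      if (is.null(e)) tmpl[NA] else e
    }, tmpl)
  })
  tibble::as_tibble(cols)
}

restore_mode <- function(type) {
  switch(type,
    numeric = numeric(1), integer = integer(1), logical = logical(1),
    character(1)
  )
}

serialize_network <- function(net) {
  list(nodes = df_to_json(net$nodes), edges = df_to_json(net$edges),
       directed = net$directed)
}

deserialize_network <- function(x) {
  make_network(df_from_json(x$nodes), df_from_json(x$edges),
               directed = isTRUE(x$directed))
}

serialize_set <- function(set) {
  cl <- set$clusters
  list(
    name = set$name,
    clusters = list(
      cluster = as.list(cl$cluster),
      members = lapply(cl$members, as.list),
      label = as.list(cl$label),
      collapsed = as.list(cl$collapsed)
    ),
    cloud_options = unclass(set$cloud_options),
    label_options = unclass(set$label_options),
    source = set$source
  )
}

deserialize_set <- function(x) {
  co <- x$cloud_options
  lo <- x$label_options
  clusters <- tibble::tibble(
    cluster = as.character(unlist(x$clusters$cluster) %||% character()),
    members = lapply(x$clusters$members, function(m) as.character(unlist(m))),
    label = vapply(x$clusters$label, function(l) l %||% "", ""),
    collapsed = as.logical(unlist(x$clusters$collapsed) %||% logical())
  )
  new_annotation_set(
    name = x$name,
    clusters = clusters,
    cloud_opts = cloud_options(
      attributes = as.character(unlist(co$attributes)),
      normalization = co$normalization,
      stopwords = as.character(unlist(co$stopwords)),
      delimiters = co$delimiters,
      min_font = co$min_font, max_font = co$max_font
    ),
    label_opts = label_options(lo$algorithm, lo$max_words, lo$size_bonus),
    source = x$source %||% "unknown"
  )
}

serialize_record <- function(r) {
  list(group_id = r$group_id, cluster_id = r$cluster_id, label = r$label,
       nodes = df_to_json(r$nodes), edges = df_to_json(r$edges),
       meta_edges = df_to_json(r$meta_edges),
       node_cols = as.list(r$node_cols), edge_cols = as.list(r$edge_cols))
}

deserialize_record <- function(x) {
  list(group_id = x$group_id, cluster_id = x$cluster_id, label = x$label,
       nodes = df_from_json(x$nodes), edges = df_from_json(x$edges),
       meta_edges = df_from_json(x$meta_edges),
       node_cols = as.character(unlist(x$node_cols)),
       edge_cols = as.character(unlist(x$edge_cols)))
}

#' Save and load annotation sessions as versioned JSON
#'
#' The session file stores the network, every annotation set with the
#' cloud and label options that produced it, the active-set marker, and
#' all collapse records, so `load_session(save_session(x))` reproduces
#' the session structurally. Files written by a newer format version are
#' refused outright (no partial load), as are corrupt files.
#'
#' @param session An [annotation_session()].
#' @param path File path.
#' @return `save_session()` returns `path` invisibly; `load_session()`
#'   returns the session.
#' @export
save_session <- function(session, path) {
  payload <- list(
    format = "netannotate-session",
    version = SESSION_FORMAT_VERSION,
    network = serialize_network(session$network),
    sets = lapply(unname(session$sets), serialize_set),
    active = session$active,
    records = lapply(session$records, serialize_record)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse session file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(raw$format, "netannotate-session")) {
    stop("'", path, "' is not a session file", call. = FALSE)
  }
  if (!identical(as.integer(raw$version), SESSION_FORMAT_VERSION)) {
    stop("session format version ", raw$version,
         " is not supported (this build reads version ",
         SESSION_FORMAT_VERSION, ")", call. = FALSE)
  }
  session <- annotation_session(deserialize_network(raw$network))
  for (s in raw$sets) {
    set <- deserialize_set(s)
    session$sets[[set$name]] <- set
  }
  session$active <- raw$active
  session$records <- lapply(raw$records, deserialize_record)
  session
}
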