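pipeline_parser <- function() {
  optparse::OptionParser(
    usage = "annotate NETWORK [options]",
    option_list = list(
      optparse::make_option("--format", type = "character", default = NULL,
        help = "network format: graphml or edgelist (default: by extension)"),
      optparse::make_option("--attrs", type = "character", default = NULL,
        help = "node attribute TSV (first column = node id)"),
      optparse::make_option("--cluster-source", type = "character",
        default = "mcl", dest = "cluster_source",
        help = "attribute | mcl | ids [default %default]"),
      optparse::make_option("--cluster-attr", type = "character",
        default = NULL, dest = "cluster_attr",
        help = "attribute holding cluster values/ids (for attribute/ids)"),
      optparse::make_option("--edge-weight", type = "character",
        default = NULL, dest = "edge_weight",
        help = "edge weight attribute for MCL"),
      optparse::make_option("--inflation", type = "double", default = 2.0,
        help = "MCL inflation [default %default]"),
      optparse::make_option("--label-attr", type = "character",
        default = "desc", dest = "label_attr",
        help = "node attribute(s) summarized into labels (comma separated)"),
      optparse::make_option("--label-algorithm", type = "character",
        default = "adjacent", dest = "label_algorithm",
        help = "adjacent | biggest [default %default]"),
      optparse::make_option("--max-words", type = "integer", default = 3,
        dest = "max_words", help = "words per label, 1-10 [default %default]"),
      optparse::make_option("--size-bonus", type = "double", default = 8,
        dest = "size_bonus", help = "adjacency size bonus [default %default]"),
      optparse::make_option("--normalization", type = "double", default = 0.5,
        help = "word-frequency normalization factor k [default %default]"),
      optparse::make_option("--shape", type = "character", default = "ellipse",
        help = "ellipse | rectangle [default %default]"),
      optparse::make_option("--opacity", type = "double", default = 0.2,
        help = "shape fill opacity [default %default]"),
      optparse::make_option("--hide-shapes", action = "store_true",
        default = FALSE, dest = "hide_shapes", help = "do not draw shapes"),
      optparse::make_option("--hide-labels", action = "store_true",
        default = FALSE, dest = "hide_labels", help = "do not draw labels"),
      optparse::make_option("--collapse-all", action = "store_true",
        default = FALSE, dest = "collapse_all",
        help = "collapse every cluster into a group node"),
      optparse::make_option("--render", type = "character", default = NULL,
        help = "write annotated SVG here"),
      optparse::make_option("--out", type = "character", default = NULL,
        help = "write (possibly collapsed) GraphML here"),
      optparse::make_option("--report", type = "character", default = NULL,
        help = "write cluster/label TSV report here"),
      optparse::make_option("--session", type = "character", default = NULL,
        help = "write JSON session here"),
      optparse::make_option("--name", type = "character",
        default = "Annotation Set", help = "annotation set name"),
      optparse::make_option("--verbose", action = "store_true",
        default = FALSE, help = "log progress to stderr")
    )
  )
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[annotate] ", ...)
}

usage_error <- function(msg) {
  structure(class = c("usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Run the end-to-end annotation pipeline
#'
#' Reads a network, clusters it (MCL or a node attribute), builds the
#' per-cluster word clouds, derives labels, optionally collapses all
#' clusters, and writes any of: an annotated SVG, the (collapsed)
#' GraphML, a cluster/label TSV report (columns `cluster`, `label`,
#' `nodes`, `collapsed`), and a JSON session. Given identical inputs the
#' pipeline is deterministic: repeated runs produce byte-identical
#' reports.
#'
#' @param args Character vector of command-line arguments (see the
#'   `annotate` script in `inst/cli/`).
#' @return Exit status, invisibly: 0 on success, 2 on usage errors, 1 on
#'   stage failures (the failing stage is named on stderr).
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  stage <- "arguments"
  status <- tryCatch({
    parsed <- optparse::parse_args2(pipeline_parser(), args = args)
    opt <- parsed$options
    if (length(parsed$args) != 1) {
      stop(usage_error("exactly one NETWORK file argument is required"))
    }
    if (opt$max_words < 1 || opt$max_words > 10) {
      stop(usage_error("--max-words must lie in 1-10"))
    }
    if (opt$cluster_source %in% c("attribute", "ids") &&
        is.null(opt$cluster_attr)) {
      stop(usage_error(paste0("--cluster-source ", opt$cluster_source,
                              " requires --cluster-attr")))
    }
    if (!opt$cluster_source %in% c("attribute", "ids", "mcl")) {
      stop(usage_error("--cluster-source must be attribute, mcl or ids"))
    }
    if (!opt$label_algorithm %in% c("adjacent", "biggest")) {
      stop(usage_error("--label-algorithm must be adjacent or biggest"))
    }

    stage <- "read network"
    path <- parsed$args
    format <- opt$format %||%
      (if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist")
    net <- read_network(path, format)
    pipeline_log(opt$verbose, "read ", nrow(net$nodes), " nodes, ",
                 nrow(net$edges), " edges from ", path)

    if (!is.null(opt$attrs)) {
      stage <- "bind attributes"
      net <- bind_attributes(net, read_attribute_table(opt$attrs))
    }

    stage <- "clustering"
    partition <- switch(opt$cluster_source,
      attribute = clusters_from_attribute(net, opt$cluster_attr),
      ids = clusters_from_attribute(net, opt$cluster_attr),
      mcl = mcl_clusters(net, opt$edge_weight, opt$inflation)
    )
    pipeline_log(opt$verbose, "clustered into ",
                 dplyr::n_distinct(stats::na.omit(partition$cluster)),
                 " clusters")

    stage <- "annotation"
    cloud_opts <- cloud_options(
      attributes = strsplit(opt$label_attr, ",", fixed = TRUE)[[1]],
      normalization = opt$normalization
    )
    label_opts <- label_options(
      algorithm = if (opt$label_algorithm == "biggest") "biggest_words"
                  else "adjacent_words",
      max_words = opt$max_words,
      size_bonus = opt$size_bonus
    )
    set <- create_annotation_set(net, partition, cloud_opts, label_opts,
                                 name = opt$name, source = opt$cluster_source)
    session <- session_add(annotation_session(net), set)

    if (opt$collapse_all) {
      stage <- "collapse"
      session <- collapse_all(session)
      pipeline_log(opt$verbose, "collapsed ", nrow(set$clusters), " clusters")
    }

    display <- display_options(
      shape = opt$shape, fill_opacity = opt$opacity,
      shapes_visible = !opt$hide_shapes, labels_visible = !opt$hide_labels
    )

    if (!is.null(opt$render)) {
      stage <- "render"
      rnet <- session$network
      if (nrow(rnet$nodes) && !all(has_positions(rnet, rnet$nodes$id))) {
        rnet <- layout_network(rnet)
        session$network <- rnet
      }
      render_svg(rnet, active_set(session), display, path = opt$render)
      pipeline_log(opt$verbose, "wrote SVG to ", opt$render)
    }
    if (!is.null(opt$out)) {
      stage <- "write network"
      write_network(session$network, opt$out, "graphml")
    }
    if (!is.null(opt$report)) {
      stage <- "report"
      readr::write_tsv(tidy(active_set(session)), opt$report, progress = FALSE)
    }
    if (!is.null(opt$session)) {
      stage <- "save session"
      save_session(session, opt$session)
    }
    0L
  },
  usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error in stage '", stage, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Assign deterministic layout coordinates to a network
#'
#' Fruchterman-Reingold layout via igraph under a fixed seed; used by
#' the pipeline when the input carries no coordinates.
#'
#' @param net A `netan_network`.
#' @param seed Seed for the layout.
#' @return The network with `x`/`y` columns filled.
#' @export
layout_network <- function(net, seed = 42) {
  g <- as_igraph(net)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  i <- match(net$nodes$id, igraph::V(g)$name)
  net$nodes$x <- xy[i, 1] * 50
  net$nodes$y <- xy[i, 2] * 50
  net
}
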