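#' Default English stopword list
#'
#' A compact list of English function words plus common connectives seen
#' in pathway and publication titles. User-extensible via the
#' `stopwords_extra` argument of [cloud_options()].
#'
#' @return Character vector of lower-case stopwords.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "and", "are", "as", "at", "be", "been", "but", "by", "can",
    "could", "did", "do", "does", "for", "from", "had", "has", "have", "if",
    "in", "into", "is", "it", "its", "may", "might", "no", "not", "of", "on",
    "or", "our", "so", "such", "than", "that", "the", "their", "then",
    "there", "these", "this", "those", "through", "to", "up", "upon", "via",
    "was", "we", "were", "which", "while", "will", "with", "within", "your"
  )
}

#' Word-cloud options
#'
#' Controls how node text is tokenized and scored into a per-cluster
#' word cloud.
#'
#' @param attributes Character vector (length >= 1) of node attribute
#'   names whose text is summarized.
#' @param normalization Normalization factor k in \[0, 1\] blending the
#'   within-cluster word frequency (k = 0: cluster counts only) with the
#'   cluster-to-network frequency ratio (larger k down-weights words
#'   that are frequent everywhere, e.g. "pathway", "regulation").
#'   Default 0.5.
#' @param stopwords Base stopword list.
#' @param stopwords_extra Additional stopwords.
#' @param delimiters Regular expression character class content used to
#'   split text into tokens. The default splits on whitespace and
#'   punctuation while keeping intra-word hyphens and underscores.
#' @param min_font,max_font Font-size range words are mapped onto.
#' @return A list of class `cloud_options`.
#' @export
cloud_options <- function(attributes,
                          normalization = 0.5,
                          stopwords = default_stopwords(),
                          stopwords_extra = character(),
                          delimiters = NULL,
                          min_font = 1,
                          max_font = 64) {
  if (missing(attributes) || !length(attributes)) {
    stop("at least one attribute name is required", call. = FALSE)
  }
  if (!is.numeric(normalization) || normalization < 0 || normalization > 1) {
    stop("`normalization` must lie in [0, 1]", call. = FALSE)
  }
  if (min_font >= max_font) stop("`min_font` must be < `max_font`", call. = FALSE)
  structure(
    list(
      attributes = as.character(attributes),
      normalization = normalization,
      stopwords = unique(c(tolower(stopwords), tolower(stopwords_extra))),
      delimiters = delimiters,
      min_font = min_font,
      max_font = max_font
    ),
    class = "cloud_options"
  )
}

#' Tokenize attribute text
#'
#' Splits on the option's delimiter set (default: anything that is not a
#' letter, digit, hyphen or underscore), lower-cases, strips leading and
#' trailing hyphens/underscores, and removes stopwords and pure numbers.
#' Original token order is preserved.
#'
#' @param text A character scalar (or vector, concatenated in order).
#' @param opts A [cloud_options()] object.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, opts) {
  text <- text[!is.na(text)]
  if (!length(text)) return(character())
  pattern <- if (is.null(opts$delimiters)) "[^\\p{L}\\p{N}_-]+"
             else paste0("[", opts$delimiters, "]+")
  toks <- unlist(stringr::str_split(tolower(text), stringr::regex(pattern)))
  toks <- gsub("^[-_]+|[-_]+$", "", toks)
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[0-9.]+$", toks)]
  toks[!toks %in% opts$stopwords]
}

#' Per-node token sequences over the selected attributes
#' @return Named list (by node id, in sorted id order) of lists of token
#'   vectors, one per attribute in the order selected.
#' @noRd
member_token_seqs <- function(net, members, opts) {
  present <- intersect(opts$attributes, names(net$nodes))
  if (!length(present)) {
    stop("none of the attributes (", paste(opts$attributes, collapse = ", "),
         ") exist on the network", call. = FALSE)
  }
  members <- sort(as.character(members))
  bad <- setdiff(members, net$nodes$id)
  if (length(bad)) stop("unknown member node(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  i <- match(members, net$nodes$id)
  seqs <- lapply(i, function(row) {
    lapply(present, function(a) {
      v <- net$nodes[[a]][row]
      if (is.na(v)) character() else tokenize(as.character(v), opts)
    })
  })
  stats::setNames(seqs, members)
}

#' Count words over the selected attributes of a node set
#'
#' Tokens are pooled across all selected attributes of all member
#' nodes; a node missing an attribute contributes nothing for it.
#'
#' @param net A `netan_network`.
#' @param members Character vector of member node ids (subset of the
#'   network's nodes). May be empty.
#' @param opts A [cloud_options()] object.
#' @return A tibble with columns `word` and `count`, ordered by first
#'   appearance (scanning members sorted by id, attributes in the order
#'   selected).
#' @export
cluster_counts <- function(net, members, opts) {
  if (!length(members)) {
    # still validate that the attributes exist somewhere
    member_token_seqs(net, character(), opts)
    return(tibble::tibble(word = character(), count = integer()))
  }
  seqs <- member_token_seqs(net, members, opts)
  toks <- unlist(seqs, use.names = FALSE)
  if (!length(toks)) return(tibble::tibble(word = character(), count = integer()))
  words <- unique(toks)  # unique() preserves first-appearance order
  tibble::tibble(word = words,
                 count = as.integer(table(factor(toks, levels = words))))
}

#' Blend cluster frequency with the cluster-to-network frequency ratio
#'
#' For each word, the within-cluster frequency `f_c = c_count /
#' cluster_total` and the enrichment ratio `f_c / f_n` (with `f_n =
#' n_count / network_total`) are each min-max rescaled to \[0, 1\]
#' across the cloud and blended as `(1 - k) * f_c' + k * ratio'`. At
#' k = 0 the score ordering equals the raw cluster-count ordering; at
#' k = 1 only the enrichment ratio matters, so words spread uniformly
#' over the network score lowest among enriched words. A degenerate
#' cloud whose values are all equal rescales to 1.
#'
#' @param c_count,n_count Word counts in the cluster and in the entire
#'   network (vectorized over the cloud; `c_count <= n_count`).
#' @param cluster_total,network_total Total token counts (positive).
#' @param k Normalization factor in \[0, 1\].
#' @return Numeric vector of non-negative scores.
#' @export
word_score <- function(c_count, cluster_total, n_count, network_total, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > 1) {
    stop("normalization factor k must lie in [0, 1]", call. = FALSE)
  }
  if (cluster_total <= 0 || network_total <= 0) {
    stop("token totals must be positive", call. = FALSE)
  }
  if (any(c_count > n_count)) {
    stop("cluster count exceeds network count", call. = FALSE)
  }
  f_c <- c_count / cluster_total
  f_n <- n_count / network_total
  ratio <- f_c / f_n
  (1 - k) * rescale01(f_c) + k * rescale01(ratio)
}

rescale01 <- function(x) {
  if (!length(x)) return(numeric())
  r <- range(x)
  if (r[1] == r[2]) return(rep(1, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Map word scores onto a font-size range
#'
#' Affine map of the score range onto `[min_font, max_font]`; when all
#' scores are equal every word sits at the maximum font.
#'
#' @param scores Named numeric vector (word -> score) or a tibble with
#'   `word` and `score` columns.
#' @param opts A [cloud_options()] object.
#' @return Named numeric vector of font sizes.
#' @export
font_sizes <- function(scores, opts) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$word)
  if (!length(scores)) stop("at least one word is required", call. = FALSE)
  r <- range(scores)
  if (r[1] == r[2]) {
    return(stats::setNames(rep(opts$max_font, length(scores)), names(scores)))
  }
  opts$min_font + (scores - r[1]) / (r[2] - r[1]) * (opts$max_font - opts$min_font)
}

#' Group words that repeatedly occur in adjacent positions
#'
#' Two words are linked when they occupy adjacent token positions in the
#' text of at least two member nodes (at least one when the cluster has
#' fewer than three members). Connected components of the resulting
#' word graph are the adjacency groups; isolated words form singleton
#' groups. Group ids are integers ordered by descending component size,
#' ties broken alphabetically by the component's smallest word.
#'
#' @param token_seqs Per-node token sequences as returned internally by
#'   the cloud builder: a list (one element per member node) of lists of
#'   token vectors (one per attribute).
#' @return Named integer vector: word -> group id, covering every
#'   distinct word in the sequences.
#' @export
adjacency_groups <- function(token_seqs) {
  n_members <- length(token_seqs)
  threshold <- if (n_members < 3) 1L else 2L
  words <- unique(unlist(token_seqs, use.names = FALSE))
  if (!length(words)) return(stats::setNames(integer(), character()))

  # per node: set of unordered adjacent pairs (counted once per node)
  pair_nodes <- list()
  for (seqs in token_seqs) {
    pairs <- character()
    for (toks in seqs) {
      if (length(toks) < 2) next
      a <- toks[-length(toks)]
      b <- toks[-1]
      keep <- a != b
      if (!any(keep)) next
      key <- paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "\r")
      pairs <- c(pairs, key)
    }
    for (p in unique(pairs)) {
      pair_nodes[[p]] <- (pair_nodes[[p]] %||% 0L) + 1L
    }
  }
  links <- names(pair_nodes)[vapply(pair_nodes, identity, 0L) >= threshold]

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(words)
  if (length(links)) {
    ends <- do.call(rbind, strsplit(links, "\r", fixed = TRUE))
    g <- g + igraph::edges(as.vector(t(ends)))
  }
  comp <- igraph::components(g)
  comp_words <- split(words, comp$membership[words])
  ord <- order(-lengths(comp_words),
               vapply(comp_words, function(w) min(w), ""))
  out <- integer(length(words))
  names(out) <- words
  for (i in seq_along(ord)) out[comp_words[[ord[i]]]] <- i
  out
}

#' Build a cluster's word cloud
#'
#' Composes tokenization, cluster and whole-network word counts, the
#' normalized score, font sizing, first-appearance order and adjacency
#' grouping into one row per distinct word. Whole-network counts range
#' over every node of the network, clustered or not. The result is
#' deterministic and independent of node iteration order (members are
#' scanned sorted by id).
#'
#' @param net A `netan_network`.
#' @param members Non-empty character vector of member node ids.
#' @param opts A [cloud_options()] object.
#' @return A tibble of class `word_cloud` with columns `word`, `size`
#'   (font size), `order` (0-based first-appearance index) and `group`
#'   (adjacency-group id). Empty attribute text yields a 0-row cloud.
#' @export
build_cloud <- function(net, members, opts) {
  if (!length(members)) stop("`members` must be non-empty", call. = FALSE)
  cc <- cluster_counts(net, members, opts)
  if (!nrow(cc)) {
    out <- tibble::tibble(word = character(), size = numeric(),
                          order = integer(), group = integer())
    class(out) <- c("word_cloud", class(out))
    return(out)
  }
  nc <- cluster_counts(net, net$nodes$id, opts)
  n_count <- nc$count[match(cc$word, nc$word)]
  scores <- word_score(cc$count, sum(cc$count), n_count, sum(nc$count),
                       opts$normalization)
  sizes <- font_sizes(stats::setNames(scores, cc$word), opts)
  groups <- adjacency_groups(member_token_seqs(net, members, opts))
  out <- tibble::tibble(
    word = cc$word,
    size = unname(sizes[cc$word]),
    order = seq_len(nrow(cc)) - 1L,
    group = unname(groups[cc$word])
  )
  class(out) <- c("word_cloud", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
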