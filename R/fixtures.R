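#' Generate a modular network with planted word themes
#'
#' Builds a planted-partition graph (edge probability `p_in` within a
#' cluster, `p_out` between clusters) whose nodes carry a text attribute
#' `desc`: a fraction `theme_fraction` of each node's words is drawn
#' from its cluster's theme vocabulary and the rest from a shared
#' background vocabulary sampled with Zipf-like weights, so a handful of
#' background fillers recur across the whole network the way words like
#' "pathway" or "regulation" recur in pathway descriptions. Theme words
#' are written as a contiguous block so adjacency grouping has phrases
#' to find. Node positions are drawn from per-cluster Gaussians around
#' centers spread on a circle, so geometry and rendering are testable.
#' All randomness is driven by `seed`; the same seed always reproduces
#' the same fixture.
#'
#' Defaults mirror the regime the package is validated in: 4 planted
#' clusters of 10 nodes, dense within (`p_in = 0.9`), sparse between
#' (`p_out = 0.02`), 10 words per node of which 80% are theme words from
#' disjoint 20-word vocabularies.
#'
#' @param n_clusters,nodes_per_cluster Planted community structure.
#' @param p_in,p_out Within/between edge probabilities; `p_in > p_out
#'   >= 0`.
#' @param theme_vocab List of `n_clusters` character vectors (disjoint
#'   theme vocabularies); `NULL` generates 20 synthetic words per theme.
#' @param background_vocab Shared vocabulary; `NULL` generates 30 filler
#'   words.
#' @param words_per_node Words in each node's `desc` attribute.
#' @param theme_fraction Fraction of a node's words drawn from its theme.
#' @param seed Integer seed.
#' @return A list with elements `network` (a `netan_network` with `desc`
#'   text and `x`/`y` positions), `partition` (ground-truth partition
#'   tibble) and `themes` (the theme vocabularies, named by cluster id).
#' @export
make_themed_network <- function(n_clusters = 4,
                                nodes_per_cluster = 10,
                                p_in = 0.9,
                                p_out = 0.02,
                                theme_vocab = NULL,
                                background_vocab = NULL,
                                words_per_node = 10,
                                theme_fraction = 0.8,
                                seed = 1) {
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_in > 1 || p_out < 0 || p_in <= p_out) {
    stop("require 1 >= p_in > p_out >= 0", call. = FALSE)
  }
  if (theme_fraction < 0 || theme_fraction > 1) {
    stop("`theme_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(theme_vocab)) {
    theme_vocab <- lapply(seq_len(n_clusters), function(k) {
      sprintf("theme%d_w%02d", k, seq_len(20))
    })
  }
  if (length(theme_vocab) != n_clusters) {
    stop("`theme_vocab` must have one vocabulary per cluster", call. = FALSE)
  }
  if (is.null(background_vocab)) {
    background_vocab <- sprintf("filler%02d", seq_len(30))
  }

  withr::with_seed(seed, {
    n <- n_clusters * nodes_per_cluster
    ids <- sprintf("n%03d", seq_len(n))
    cl <- rep(seq_len(n_clusters), each = nodes_per_cluster)

    pairs <- utils::combn(n, 2)
    same <- cl[pairs[1, ]] == cl[pairs[2, ]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- tibble::tibble(from = ids[pairs[1, keep]], to = ids[pairs[2, keep]])

    n_theme <- round(theme_fraction * words_per_node)
    bg_w <- 1 / seq_along(background_vocab)  # Zipf-like filler reuse
    desc <- vapply(seq_len(n), function(i) {
      tw <- if (n_theme > 0) {
        sample(theme_vocab[[cl[i]]], n_theme, replace = TRUE)
      } else character()
      bw <- if (words_per_node - n_theme > 0) {
        sample(background_vocab, words_per_node - n_theme,
               replace = TRUE, prob = bg_w)
      } else character()
      paste(c(tw, bw), collapse = " ")
    }, "")

    ang <- 2 * pi * (seq_len(n_clusters) - 1) / n_clusters
    cx <- 200 * cos(ang)
    cy <- 200 * sin(ang)
    nodes <- tibble::tibble(
      id = ids,
      x = stats::rnorm(n, cx[cl], 30),
      y = stats::rnorm(n, cy[cl], 30),
      desc = desc
    )

    list(
      network = make_network(nodes, edges),
      partition = new_partition(ids, as.character(cl)),
      themes = stats::setNames(theme_vocab, as.character(seq_len(n_clusters)))
    )
  })
}
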