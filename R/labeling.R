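#' Label options
#'
#' The shipped default is the adjacency-aware selector with a size bonus
#' of 8 and 3-word labels; labels never exceed 10 words.
#'
#' @param algorithm `"adjacent_words"` (default) or `"biggest_words"`.
#' @param max_words Maximum words per label, integer in \[1, 10\].
#' @param size_bonus Non-negative size bonus granted to words sharing an
#'   adjacency group with the current top words (default 8). Only used
#'   by `adjacent_words`.
#' @return A list of class `label_options`.
#' @export
label_options <- function(algorithm = c("adjacent_words", "biggest_words"),
                          max_words = 3,
                          size_bonus = 8) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(max_words) || max_words != as.integer(max_words) ||
      max_words < 1 || max_words > 10) {
    stop("`max_words` must be an integer in [1, 10]", call. = FALSE)
  }
  if (!is.numeric(size_bonus) || size_bonus < 0) {
    stop("`size_bonus` must be non-negative", call. = FALSE)
  }
  structure(
    list(algorithm = algorithm, max_words = as.integer(max_words),
         size_bonus = size_bonus),
    class = "label_options"
  )
}

# sort indices by descending size then ascending order (earlier
# first-appearance wins ties)
size_rank <- function(size, order) order(-size, order)

#' Select the N biggest cloud words, emitted in appearance order
#'
#' Sorts the cloud by font size (ties broken by earlier first
#' appearance), takes the `n` largest words, then re-sorts the selection
#' by word order so the label reads like the source text.
#'
#' @param cloud A `word_cloud` tibble (columns `word`, `size`, `order`,
#'   `group`).
#' @param n Maximum number of words.
#' @return Character vector of at most `n` words (empty for an empty
#'   cloud).
#' @export
select_biggest_words <- function(cloud, n) {
  if (!nrow(cloud)) return(character())
  top <- size_rank(cloud$size, cloud$order)[seq_len(min(n, nrow(cloud)))]
  sel <- cloud[top, ]
  sel$word[order(sel$order)]
}

#' Select label words balancing size with adjacency grouping
#'
#' Identifies the `n` largest words, then grants every word sharing an
#' adjacency group with any of them a size bonus, capped so that no word
#' can outgrow the largest word of its own adjacency group. The list is
#' re-sorted by boosted size, the `n` largest are taken, and the result
#' is emitted in word order. With `bonus = 0`, or when every word sits
#' in its own singleton group, the output equals
#' [select_biggest_words()].
#'
#' @inheritParams select_biggest_words
#' @param bonus Non-negative size bonus (default 8).
#' @return Character vector of at most `n` words.
#' @export
select_adjacent_words <- function(cloud, n, bonus = 8) {
  if (!nrow(cloud)) return(character())
  top <- size_rank(cloud$size, cloud$order)[seq_len(min(n, nrow(cloud)))]
  top_groups <- unique(cloud$group[top])
  group_max <- tapply(cloud$size, cloud$group, max)
  boosted <- ifelse(
    cloud$group %in% top_groups,
    pmin(cloud$size + bonus, unname(group_max[as.character(cloud$group)])),
    cloud$size
  )
  sel <- cloud[size_rank(boosted, cloud$order)[seq_len(min(n, nrow(cloud)))], ]
  sel$word[order(sel$order)]
}

#' Join selected words into a label string
#' @param words Character vector (possibly empty).
#' @return A single string; empty input gives `""`.
#' @export
make_label <- function(words) paste(words, collapse = " ")

#' Compute a cluster label from its word cloud
#' @param cloud A `word_cloud` tibble.
#' @param label_opts A [label_options()] object.
#' @return Label string.
#' @export
label_from_cloud <- function(cloud, label_opts = label_options()) {
  words <- switch(label_opts$algorithm,
    biggest_words = select_biggest_words(cloud, label_opts$max_words),
    adjacent_words = select_adjacent_words(cloud, label_opts$max_words,
                                           label_opts$size_bonus)
  )
  make_label(words)
}
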