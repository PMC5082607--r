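# Shared fixtures and independent oracles.

# Build a word_cloud tibble from parallel vectors.
make_cloud <- function(word, size, order = seq_along(word) - 1L,
                       group = seq_along(word)) {
  out <- tibble::tibble(word = word, size = as.numeric(size),
                        order = as.integer(order), group = as.integer(group))
  class(out) <- c("word_cloud", class(out))
  out
}

# Random cloud with occasional size ties; orders are distinct.
random_cloud <- function(max_words = 8) {
  n <- sample(1:max_words, 1)
  make_cloud(
    word = paste0("w", sample(1000, n)),
    size = sample(seq(2, 40, by = 2), n, replace = TRUE),
    order = sample(0:(n + 3), n),
    group = sample(1:max(1, n %/% 2), n, replace = TRUE)
  )
}

# Brute-force selection oracle: enumerate every size-n subset, keep the
# ones with maximal total font size, break ties by minimal sum of order
# values (orders are distinct, so this is unique), and emit the winner's
# words sorted by order. Independent of the greedy implementation.
oracle_biggest <- function(cloud, n) {
  m <- nrow(cloud)
  if (m == 0) return(character())
  k <- min(n, m)
  subsets <- utils::combn(m, k, simplify = FALSE)
  tot <- vapply(subsets, function(s) sum(cloud$size[s]), 0)
  best <- subsets[tot == max(tot)]
  if (length(best) > 1) {
    osum <- vapply(best, function(s) sum(cloud$order[s]), 0)
    best <- best[osum == min(osum)]
  }
  s <- best[[1]]
  cloud$word[s][order(cloud$order[s])]
}

# Tiny labeled network: nodes carry a "desc" text attribute.
text_net <- function(desc, edges = NULL, positions = NULL) {
  nodes <- tibble::tibble(id = names(desc), desc = unname(desc))
  if (!is.null(positions)) {
    nodes$x <- positions[, 1]
    nodes$y <- positions[, 2]
  }
  make_network(nodes, edges)
}

# Compare two data frames as row multisets, ignoring row order and
# attribute metadata.
expect_same_rows <- function(a, b) {
  canon <- function(d) {
    d <- as.data.frame(d)[sort(names(d))]
    d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  expect_equal(canon(a), canon(b), ignore_attr = TRUE)
}

# Partition tibble -> named member list, for readable expectations.
partition_list <- function(p) {
  mem <- partition_members(p)
  stats::setNames(mem$members, mem$cluster)
}
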