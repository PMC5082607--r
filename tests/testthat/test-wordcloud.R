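opts1 <- cloud_options("desc")

test_that("tokenize lower-cases, splits, keeps hyphens, drops stopwords/numbers", {
  expect_equal(tokenize("Regulation of the apoptosis pathway", opts1),
               c("regulation", "apoptosis", "pathway"))
  expect_equal(tokenize("", opts1), character())
  expect_equal(tokenize("TGF-beta signaling; TGF-beta receptor", opts1),
               c("tgf-beta", "signaling", "tgf-beta", "receptor"))
  expect_equal(tokenize("phase 2 checkpoint (G2/M)", opts1),
               c("phase", "checkpoint", "g2", "m"))
  expect_equal(tokenize(NA_character_, opts1), character())
})

test_that("cluster_counts pools tokens over members and attributes", {
  net <- text_net(c(a = "cell cycle", b = "cell cycle", c = "cell cycle"))
  cc <- cluster_counts(net, c("a", "b", "c"), opts1)
  expect_equal(cc, tibble::tibble(word = c("cell", "cycle"), count = c(3L, 3L)))

  expect_equal(nrow(cluster_counts(net, character(), opts1)), 0)
  expect_error(cluster_counts(net, "a", cloud_options("nope")), "exist")

  two <- make_network(tibble::tibble(id = "a", desc = "dna repair",
                                     title = "dna damage"))
  cc2 <- cluster_counts(two, "a", cloud_options(c("desc", "title")))
  expect_equal(cc2$count[cc2$word == "dna"], 2L)
  expect_equal(cc2$count[cc2$word == "repair"], 1L)
})

test_that("word_score reproduces the stated normalization limits", {
  # k = 0: ranking equals raw cluster counts
  s0 <- word_score(c(5, 3, 1), 9, c(50, 3, 10), 100, k = 0)
  expect_equal(order(s0), order(c(5, 3, 1)))

  # the cluster-enriched word beats the network-ubiquitous one at k = 0.5
  s <- word_score(c(5, 5), 10, c(50, 5), 100, k = 0.5)
  expect_gt(s[2], s[1])  # oocyte (exclusive) > pathway (ubiquitous)

  # uniformly spread word (f_c = f_n) at k = 1 is minimal among enriched
  s1 <- word_score(c(2, 2), 4, c(4, 40), 80, k = 1)
  # word 1: ratio 0.5/(0.05) = 10; word 2: ratio 0.5/0.5 = 1
  expect_equal(s1, c(1, 0))

  expect_error(word_score(1, 2, 1, 4, k = 1.5), "\\[0, 1\\]")
  expect_error(word_score(5, 2, 1, 4, k = 0.5), "exceeds")
})

test_that("font sizes map affinely with degenerate range at max font", {
  o <- cloud_options("desc", min_font = 1, max_font = 64)
  expect_equal(unname(font_sizes(c(a = 1, b = 1), o)), c(64, 64))
  expect_equal(unname(font_sizes(c(a = 0, b = 1), o)), c(1, 64))
  expect_equal(unname(font_sizes(c(a = 0, b = 0.5, c = 1), o))[2], 32.5)
})

test_that("adjacency groups link repeatedly adjacent words transitively", {
  seqs3 <- replicate(3, list(list(c("mitotic", "cell", "cycle"))),
                     simplify = FALSE)
  seqs3 <- lapply(seqs3, `[[`, 1)
  g <- adjacency_groups(seqs3)
  expect_equal(g[["cell"]], g[["cycle"]])

  # never-adjacent words: all singleton groups
  g2 <- adjacency_groups(list(list(c("alpha")), list(c("beta")),
                              list(c("gamma"))))
  expect_length(unique(g2), 3)

  # chain a-b (2 nodes) + b-c (2 nodes) merges into one group of 3
  g3 <- adjacency_groups(list(
    list(c("a", "b")), list(c("a", "b")),
    list(c("b", "c")), list(c("b", "c"))
  ))
  expect_length(unique(g3[c("a", "b", "c")]), 1)

  # with < 3 members a single co-occurrence suffices
  g4 <- adjacency_groups(list(list(c("x", "y"))))
  expect_equal(g4[["x"]], g4[["y"]])

  # with >= 3 members one co-occurrence is not enough
  g5 <- adjacency_groups(list(list(c("x", "y")), list(character()),
                              list(character())))
  expect_false(g5[["x"]] == g5[["y"]])
})

test_that("build_cloud composes counts, scores, sizes, order and groups", {
  net <- text_net(c(a = "dna repair", b = "dna repair"))
  cloud <- build_cloud(net, c("a", "b"), opts1)
  expect_equal(cloud$word, c("dna", "repair"))
  expect_equal(cloud$size, c(64, 64))       # equal scores -> max font
  expect_equal(cloud$order, c(0L, 1L))
  expect_length(unique(cloud$group), 1)     # adjacent in both members

  single <- text_net(c(a = "apoptosis"))
  c1 <- build_cloud(single, "a", opts1)
  expect_equal(c1$size, 64)
  expect_equal(c1$order, 0L)

  blank <- text_net(c(a = "", b = ""))
  expect_equal(nrow(build_cloud(blank, c("a", "b"), opts1)), 0)
  expect_error(build_cloud(net, character(), opts1), "non-empty")
})

test_that("build_cloud is independent of member order and covers all tokens", {
  net <- text_net(c(
    a = "cell cycle checkpoint", b = "cell cycle arrest",
    c = "dna repair pathway", d = "cell division"
  ))
  c1 <- build_cloud(net, c("a", "b", "d"), opts1)
  c2 <- build_cloud(net, c("d", "b", "a"), opts1)
  expect_identical(c1, c2)
  toks <- unique(unlist(lapply(c("a", "b", "d"), function(i) {
    tokenize(net$nodes$desc[net$nodes$id == i], opts1)
  })))
  expect_setequal(c1$word, toks)
  expect_false(anyDuplicated(c1$word) > 0)
  expect_false(anyDuplicated(c1$order) > 0)
  expect_true(all(c1$size > 0))
})

test_that("k = 0 score order equals cluster count order on random fixtures", {
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(2:12, 1)
      c_count <- sample(1:20, n, replace = TRUE)
      n_count <- c_count + sample(0:30, n, replace = TRUE)
      s <- word_score(c_count, sum(c_count), n_count,
                      sum(n_count) + sample(10:100, 1), k = 0)
      expect_equal(rank(s), rank(c_count))
    }
  })
})

test_that("raising k never demotes a cluster-exclusive word below an equally
           counted ubiquitous one", {
  withr::with_seed(43, {
    for (i in 1:20) {
      cc <- sample(2:6, 1)
      extra <- sample(1:5, 3, replace = TRUE)
      c_count <- c(cc, cc, extra)                # [exclusive, ubiquitous, ...]
      n_count <- c(cc, cc * sample(5:20, 1), extra + sample(5:40, 3))
      above <- NA
      prev <- -Inf
      for (k in c(0, 0.25, 0.5, 0.75, 1)) {
        s <- word_score(c_count, sum(c_count), n_count, sum(n_count), k)
        diff <- s[1] - s[2]
        expect_gte(diff, prev - 1e-12)
        prev <- diff
      }
    }
  })
})
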