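test_that("collapse replaces members with a labeled group node and meta-edges", {
  net <- make_network(
    c("a", "b", "e"),
    tibble::tibble(from = c("a", "a"), to = c("b", "e"))
  )
  res <- collapse_cluster(net, c("a", "b"), "c1", label = "my label")
  n2 <- res$network
  expect_setequal(n2$nodes$id, c("e", "group:c1"))
  expect_equal(n2$nodes$name[n2$nodes$id == "group:c1"], "my label")
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$from, "group:c1")
  expect_equal(n2$edges$to, "e")
  expect_equal(n2$edges$count, 1L)
  expect_true(n2$edges$is_meta)

  # external node adjacent to both members: one meta-edge, count 2
  net2 <- make_network(
    c("a", "b", "e"),
    tibble::tibble(from = c("a", "a", "b"), to = c("b", "e", "e"))
  )
  res2 <- collapse_cluster(net2, c("a", "b"), "c1")
  expect_equal(nrow(res2$network$edges), 1)
  expect_equal(res2$network$edges$count, 2L)

  # no boundary: isolated group node
  iso <- collapse_cluster(make_network(c("a", "b"),
                                       tibble::tibble(from = "a", to = "b")),
                          c("a", "b"), "c1")
  expect_equal(nrow(iso$network$edges), 0)

  expect_error(collapse_cluster(res$network, "e", "c1"), "already collapsed")
})

test_that("group node sits at the member centroid", {
  net <- make_network(tibble::tibble(id = c("a", "b"), x = c(0, 10),
                                     y = c(0, 20)))
  res <- collapse_cluster(net, c("a", "b"), "c1")
  g <- res$network$nodes[res$network$nodes$id == "group:c1", ]
  expect_equal(c(g$x, g$y), c(5, 10))
})

test_that("expand restores the pre-collapse network exactly", {
  fx <- make_themed_network(n_clusters = 2, nodes_per_cluster = 5, seed = 4)
  members <- partition_list(fx$partition)[["1"]]
  res <- collapse_cluster(fx$network, members, "1", "L")
  back <- expand_cluster(res$network, res$record)
  expect_same_rows(back$nodes, fx$network$nodes)
  expect_same_rows(back$edges, fx$network$edges)

  expect_error(expand_cluster(back, res$record), "missing")
})

test_that("session collapse/expand keeps flags, annotations and counts", {
  fx <- make_themed_network(seed = 5)
  set <- create_annotation_set(fx$network, fx$partition,
                               cloud_options("desc"), name = "A")
  s <- session_add(annotation_session(fx$network), set)
  k <- nrow(set$clusters)
  n0 <- nrow(fx$network$nodes)

  s2 <- collapse_all(s)
  expect_true(all(s2$sets$A$clusters$collapsed))
  # node count = original - sum(|members|) + k
  expect_equal(nrow(s2$network$nodes),
               n0 - sum(lengths(set$clusters$members)) + k)
  # collapsed clusters are not drawn as shapes
  doc <- render_svg(s2$network, s2$sets$A)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='ellipse']"), 0)

  s3 <- expand_all(s2)
  expect_false(any(s3$sets$A$clusters$collapsed))
  expect_same_rows(s3$network$nodes, fx$network$nodes)
  expect_same_rows(s3$network$edges, fx$network$edges)
  expect_length(s3$records, 0)

  # double-expand errors; collapse_all with no clusters is a no-op
  expect_error(session_expand(s3, "1"), "not collapsed")
  empty_set <- create_annotation_set(fx$network,
                                     partition_from_ids(fx$network, list()),
                                     cloud_options("desc"), name = "E")
  se <- session_add(annotation_session(fx$network), empty_set)
  expect_same_rows(collapse_all(se)$network$nodes, fx$network$nodes)
})

test_that("two adjacent collapsed clusters share exactly one meta-edge", {
  net <- make_network(
    c("a1", "a2", "b1", "b2"),
    tibble::tibble(from = c("a1", "b1", "a1", "a2"),
                   to   = c("a2", "b2", "b1", "b2"))
  )
  p <- partition_from_ids(net, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  resA <- collapse_cluster(net, c("a1", "a2"), "A")
  resB <- collapse_cluster(resA$network, c("b1", "b2"), "B")
  e <- resB$network$edges
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$from, e$to), c("group:B", "group:A"))

  # reverse-order expansion restores the original network
  back <- expand_cluster(expand_cluster(resB$network, resB$record),
                         resA$record)
  expect_same_rows(back$nodes, net$nodes)
  expect_same_rows(back$edges, net$edges)
})

test_that("meta-edges match a brute-force boundary scan on random fixtures", {
  withr::with_seed(15, {
    for (i in 1:15) {
      fx <- make_themed_network(n_clusters = 3, nodes_per_cluster = 4,
                                p_in = 0.7, p_out = 0.2, seed = i)
      members <- partition_list(fx$partition)[["2"]]
      res <- collapse_cluster(fx$network, members, "2")
      meta <- res$network$edges[res$network$edges$is_meta %in% TRUE, ]
      e <- fx$network$edges
      boundary <- e[xor(e$from %in% members, e$to %in% members), ]
      ext <- ifelse(boundary$from %in% members, boundary$to, boundary$from)
      want <- table(ext)
      expect_setequal(meta$to, names(want))
      expect_equal(meta$count[match(names(want), meta$to)],
                   as.integer(want))
    }
  })
})
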