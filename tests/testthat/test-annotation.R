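themed_setup <- function(seed = 2) {
  fx <- make_themed_network(n_clusters = 3, nodes_per_cluster = 5, seed = seed)
  set <- create_annotation_set(fx$network, fx$partition,
                               cloud_options("desc"), label_options(), "S1")
  list(fx = fx, set = set)
}

test_that("annotation sets label every cluster reproducibly", {
  st <- themed_setup()
  expect_equal(nrow(st$set$clusters), 3)
  expect_true(all(nzchar(st$set$clusters$label)))
  expect_false(any(st$set$clusters$collapsed))

  again <- create_annotation_set(st$fx$network, st$fx$partition,
                                 cloud_options("desc"), label_options(), "S1")
  expect_identical(tidy(st$set), tidy(again))

  # empty partition -> empty but valid set
  net <- make_network(c("a", "b"))
  p <- partition_from_ids(net, list())
  empty <- create_annotation_set(net, p, cloud_options("desc"),
                                 name = "E")
  expect_equal(nrow(empty$clusters), 0)
})

test_that("sessions hold many sets but a single active one; duplicate names
           are rejected; switching requires expanded clusters", {
  st <- themed_setup()
  other <- create_annotation_set(st$fx$network, st$fx$partition,
                                 cloud_options("desc"),
                                 label_options("biggest_words"), "S2")
  s <- session_add(annotation_session(st$fx$network), st$set)
  s <- session_add(s, other)
  expect_equal(s$active, "S1")
  expect_error(session_add(s, st$set), "already exists")

  s <- set_active(s, "S2")
  expect_equal(s$active, "S2")
  s <- set_active(s, NULL)
  expect_null(s$active)
  expect_null(netannotate:::active_set(s))

  s <- set_active(s, "S1")
  s <- session_collapse(s, s$sets$S1$clusters$cluster[1])
  expect_error(set_active(s, "S2"), "expand")
  s <- session_expand(s, s$sets$S1$clusters$cluster[1])
  expect_silent(s <- set_active(s, "S2"))
})

test_that("merge_clusters unions members and relabels", {
  st <- themed_setup()
  ids <- st$set$clusters$cluster[1:2]
  merged <- merge_clusters(st$set, st$fx$network, ids)
  expect_equal(nrow(merged$clusters), 2)
  i <- match(ids[1], merged$clusters$cluster)
  expect_length(merged$clusters$members[[i]], 10)
  expect_true(nzchar(merged$clusters$label[i]))

  expect_error(merge_clusters(st$set, st$fx$network, c(ids[1], ids[1])),
               "distinct")
  expect_error(merge_clusters(st$set, st$fx$network, c(ids[1], "zzz")),
               "unknown")

  all_ids <- st$set$clusters$cluster
  one <- merge_clusters(st$set, st$fx$network, all_ids)
  expect_equal(nrow(one$clusters), 1)
  expect_setequal(one$clusters$members[[1]], st$fx$network$nodes$id)
})

test_that("creating clusters from selections moves overlapping nodes", {
  st <- themed_setup()
  sel <- c(st$set$clusters$members[[1]][1:2], st$set$clusters$members[[2]][1])
  out <- create_cluster_from_selection(st$set, st$fx$network, sel)
  expect_silent(netannotate:::check_disjoint(out))
  newest <- out$clusters[nrow(out$clusters), ]
  expect_setequal(newest$members[[1]], sel)
  expect_error(create_cluster_from_selection(st$set, st$fx$network,
                                             character()), "empty")

  # selection equal to an existing cluster replaces it
  whole <- st$set$clusters$members[[1]]
  out2 <- create_cluster_from_selection(st$set, st$fx$network, whole)
  expect_equal(nrow(out2$clusters), 3)
  expect_silent(netannotate:::check_disjoint(out2))
})

test_that("relabel sets text verbatim or recomputes under new options", {
  st <- themed_setup()
  id <- st$set$clusters$cluster[1]
  manual <- relabel(st$set, st$fx$network, id, label = "cell cycle")
  expect_equal(manual$clusters$label[1], "cell cycle")
  empty <- relabel(st$set, st$fx$network, id, label = "")
  expect_equal(empty$clusters$label[1], "")

  shorter <- st$set
  shorter$label_options <- label_options(max_words = 1)
  re <- relabel(shorter, st$fx$network, id, recompute = TRUE)
  expect_length(strsplit(re$clusters$label[1], " ")[[1]], 1)
  expect_error(relabel(st$set, st$fx$network, "zzz", label = "x"), "unknown")
})

test_that("cluster geometry pads the bounding box and tracks layout", {
  net <- make_network(tibble::tibble(id = c("a", "b"),
                                     x = c(0, 100), y = c(0, 40)))
  cl <- list(members = c("a", "b"), label = "L")
  g <- cluster_geometry(net, cl, padding = 10)
  expect_equal(unlist(g$shape[c("x", "y", "w", "h")]),
               c(x = -10, y = -10, w = 120, h = 60))
  expect_equal(g$label$x, 50)
  expect_lt(g$label$y, g$shape$y)  # label sits above the top edge

  point <- make_network(tibble::tibble(id = "a", x = 0, y = 0))
  gp <- cluster_geometry(point, list(members = "a", label = ""), padding = 10)
  expect_equal(unlist(gp$shape[c("x", "y", "w", "h")]),
               c(x = -10, y = -10, w = 20, h = 20))

  # geometry follows moved nodes: no stale positions
  net$nodes$x[2] <- 200
  g2 <- cluster_geometry(net, cl, padding = 10)
  expect_equal(g2$shape$w, 220)

  nopos <- make_network(tibble::tibble(id = c("a", "b"), x = c(0, NA),
                                       y = c(0, NA)))
  expect_error(cluster_geometry(nopos, cl), "b")
})

test_that("font scaling grows label font sublinearly with cluster size", {
  net <- make_network(tibble::tibble(id = paste0("n", 1:10),
                                     x = 1:10, y = 1:10))
  d <- display_options(base_font = 12, font_scaling = TRUE)
  g <- cluster_geometry(net, list(members = paste0("n", 1:10), label = "x"), d)
  expect_equal(g$label$font_size, 12 * (1 + log10(10)))
  d0 <- display_options(base_font = 12, font_scaling = FALSE)
  g0 <- cluster_geometry(net, list(members = paste0("n", 1:10), label = "x"), d0)
  expect_equal(g0$label$font_size, 12)
})

test_that("member positions always fall inside the cluster shape", {
  withr::with_seed(13, {
    for (i in 1:10) {
      fx <- make_themed_network(n_clusters = 2, nodes_per_cluster = 6,
                                seed = i)
      set <- create_annotation_set(fx$network, fx$partition,
                                   cloud_options("desc"), name = "A")
      for (r in seq_len(nrow(set$clusters))) {
        g <- cluster_geometry(fx$network, set$clusters[r, ])
        m <- match(set$clusters$members[[r]], fx$network$nodes$id)
        expect_true(all(fx$network$nodes$x[m] >= g$shape$x &
                        fx$network$nodes$x[m] <= g$shape$x + g$shape$w))
        expect_true(all(fx$network$nodes$y[m] >= g$shape$y &
                        fx$network$nodes$y[m] <= g$shape$y + g$shape$h))
      }
    }
  })
})

test_that("random edit sequences preserve cluster disjointness", {
  withr::with_seed(14, {
    st <- themed_setup()
    set <- st$set
    net <- st$fx$network
    for (step in 1:30) {
      op <- sample(c("merge", "select", "relabel"), 1)
      if (op == "merge" && nrow(set$clusters) >= 2) {
        ids <- sample(set$clusters$cluster, 2)
        set <- merge_clusters(set, net, ids)
      } else if (op == "select") {
        sel <- sample(net$nodes$id, sample(1:5, 1))
        set <- create_cluster_from_selection(set, net, sel)
      } else {
        id <- sample(set$clusters$cluster, 1)
        set <- relabel(set, net, id, label = paste("manual", step))
      }
      expect_silent(netannotate:::check_disjoint(set))
    }
  })
})

test_that("tidy and glance summarize annotation sets", {
  st <- themed_setup()
  td <- tidy(st$set)
  expect_named(td, c("cluster", "label", "nodes", "collapsed"))
  expect_equal(sum(td$nodes), 15)
  gl <- glance(st$set)
  expect_equal(gl$n_clusters, 3)
  expect_equal(gl$algorithm, "adjacent_words")
  expect_equal(gl$size_bonus, 8)
})
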