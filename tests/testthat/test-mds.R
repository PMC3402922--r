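test_that("active degree counts only edges to non-compressed neighbors", {
  path <- make_path(3)
  expect_equal(active_degree(path, "b"), 2)
  expect_equal(active_degree(path, "b", compressed = "a"), 1)
  recip <- reaction_network(data.frame(from = c("a", "b"), to = c("b", "a")))
  expect_equal(active_degree(recip, "a"), 2)
  expect_error(active_degree(path, "zz"), "not in network")
})

test_that("a single compression step merges one minimum-degree pair", {
  one <- reaction_network(data.frame(from = "a", to = "b"))
  lv <- mds_level(one)
  expect_equal(lv$network$nodes, "a+b")
  expect_equal(n_edges(lv$network), 0)
  expect_equal(unname(lv$supernodes$internal_edges[[1]]), cbind("a", "b"))

  tri <- reaction_network(data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")))
  st <- mds_step(mds_state(tri))
  expect_equal(st$merges[[1]], c("a", "b"))
  # after merging a with b, node c has active degree zero
  expect_error(mds_step(st), "no non-compressed node")
})

test_that("one MDS level reproduces the worked-example compressions", {
  toy <- toy_instance()
  lv1 <- mds_level(toy$net1)
  expect_setequal(lv1$network$nodes, c("a+b", "c", "d+e"))
  expect_equal(unname(lv1$network$edges),
               cbind(c("a+b", "a+b"), c("c", "d+e")))
  lv2 <- mds_level(toy$net2)
  expect_setequal(lv2$network$nodes, c("a'+b'", "c'+d'"))
  expect_equal(unname(lv2$network$edges), cbind("a'+b'", "c'+d'"))

  edgeless <- reaction_network(nodes = c("x", "y", "z"))
  lv0 <- mds_level(edgeless)
  expect_setequal(lv0$network$nodes, c("x", "y", "z"))
  expect_equal(nrow(lv0$steps), 0)
})

test_that("multilevel compression halves paths and validates arguments", {
  net <- make_path(8)
  h <- mds_compress(net, 3)
  expect_length(h$levels, 4)
  expect_equal(n_nodes(h$levels[[4]]), 1)
  expect_error(mds_compress(net, -1), "non-negative")

  h0 <- mds_compress(net, 0)
  expect_equal(h0$levels[[1]], net)
  expect_length(h0$levels, 1)

  toy <- toy_instance()
  expect_equal(vapply(mds_compress(toy$net1, 1)$levels, n_nodes, integer(1)),
               c(5L, 3L))
})

test_that("each step removes exactly one node and at least one edge", {
  for (seed in 1:5) {
    net <- scale_free_network(40, seed = seed)
    h <- mds_compress(net, 3)
    counts <- tidy(h)
    expect_equal(diff(counts$nodes), -counts$steps[-1])
    expect_true(all(diff(counts$edges) <= -counts$steps[-1]))
    # member-count bound and termination bound per level
    for (lv in h$levels) {
      mem <- lengths(metalign:::node_members(lv))
      expect_true(all(mem >= 1 & mem <= 2^lv$level))
    }
    expect_true(all(counts$steps[-1] <= floor(counts$nodes[-length(counts$nodes)] / 2)))
  }
})

test_that("compression is deterministic and pure", {
  net <- scale_free_network(30, seed = 11)
  expect_equal(mds_compress(net, 2), mds_compress(net, 2))
})

test_that("randomized compression is seed-reproducible and tie-insensitive on forced graphs", {
  # degree sequence forces the same merges whatever the tie-break
  forced <- reaction_network(data.frame(from = c("a", "a", "b", "c"),
                                        to = c("b", "c", "c", "d")))
  det <- mds_compress(forced, 1)
  for (seed in 1:5) {
    rnd <- mds_compress_randomized(forced, 1, seed)
    expect_equal(rnd$levels, det$levels)
    expect_equal(rnd$supernodes, det$supernodes)
  }

  path4 <- make_path(4)
  expect_equal(nrow(mds_compress_randomized(path4, 1, 1)$steps), 2)
  expect_equal(nrow(mds_compress_randomized(path4, 1, 2)$steps), 2)

  net <- scale_free_network(30, seed = 5)
  expect_equal(mds_compress_randomized(net, 2, 42),
               mds_compress_randomized(net, 2, 42))
})

test_that("decompressing a block recovers the encapsulated connectivity", {
  toy <- toy_instance()
  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  blk <- decompress_block(h1, 1, "d+e")
  expect_equal(unname(blk$edges), cbind("d", "e"))
  blk2 <- decompress_block(h2, 1, "c'+d'")
  expect_equal(unname(blk2$edges), cbind("c'", "d'"))
  single <- decompress_block(h1, 1, "c")
  expect_equal(single$nodes, "c")
  expect_equal(n_edges(single), 0)
  expect_error(decompress_block(h1, 1, "zz"), "does not exist")
})

test_that("decompressing all nodes of a level reconstructs the level below", {
  for (seed in 1:4) {
    net <- scale_free_network(25, seed = seed)
    h <- mds_compress(net, 3)
    for (x in seq_len(max_level(h))) {
      rebuilt <- decompress_block(h, x, h$levels[[x + 1]]$nodes)
      expect_equal(rebuilt$nodes, h$levels[[x]]$nodes)
      expect_equal(rebuilt$edges, h$levels[[x]]$edges)
    }
  }
})
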