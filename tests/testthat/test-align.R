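test_that("connected subnetworks of bounded size are enumerated exactly once", {
  path3 <- make_path(3)
  expect_equal(nrow(enumerate_subnetworks(path3, 1)), 3)
  expect_equal(nrow(enumerate_subnetworks(path3, 2)), 5)
  expect_equal(nrow(enumerate_subnetworks(path3, 3)), 6)
  expect_error(enumerate_subnetworks(path3, 0), "positive")

  for (seed in 1:6) {
    net <- random_net(6 + seed %% 2, p = 0.3, seed = seed)
    for (k in 1:3) {
      subs <- enumerate_subnetworks(net, k)
      expect_equal(anyDuplicated(subs$id), 0L)
      expect_equal(sort(subs$id), oracle_connected_sets(net, k))
    }
  }
})

test_that("candidate mappings respect the one-to-many constraint", {
  toy <- toy_instance()
  s1 <- enumerate_subnetworks(toy$net1, 1)
  s2 <- enumerate_subnetworks(toy$net2, 1)
  cands <- candidate_mappings(s1, s2, toy$sim)
  expect_equal(nrow(cands), 20)

  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  cc <- candidate_mappings(enumerate_subnetworks(h1$levels[[2]], 1),
                           enumerate_subnetworks(h2$levels[[2]], 1), toy$sim)
  expect_equal(nrow(cc), 6)
  expect_true(all(pmin(cc$left_size, cc$right_size) == 1))
  # supernode homology averages reaction similarities over the cross product
  expect_equal(cc$homology[cc$mapping_id == "a+b|a'+b'"], 0.55)
  expect_equal(cc$homology[cc$mapping_id == "d+e|c'+d'"], 0.325)

  unif <- candidate_mappings(s1, s2, "uniform")
  expect_true(all(unif$homology == unif$homology[1]))

  bad_sim <- toy$sim[-1, , drop = FALSE]
  expect_error(candidate_mappings(s1, s2, bad_sim), "missing identifier 'a'")
})

test_that("with k > 1 one-to-many candidates average over all member pairs", {
  toy <- toy_instance()
  s1 <- enumerate_subnetworks(toy$net1, 1)
  s2 <- enumerate_subnetworks(toy$net2, 2)
  cands <- candidate_mappings(s1, s2, toy$sim)
  # b against the pair {b', c'}: mean(1.0, 0.1)
  expect_equal(cands$homology[cands$mapping_id == "b|b',c'"], 0.55)
  expect_false(any(cands$left_size > 1 & cands$right_size > 1))
})

test_that("the support matrix spreads unit support over neighbor mappings", {
  toy <- toy_instance()
  al <- align_networks(toy$net1, toy$net2, k = 1, sim = toy$sim)
  S <- build_support(al$candidates, toy$net1, toy$net2)
  expect_equal(dim(S), c(20L, 20L))
  col <- S[, "b|b'"]
  expect_equal(sort(names(col[col != 0])),
               sort(c("a|a'", "c|c'", "c|d'", "d|c'", "d|d'")))
  expect_true(all(col[col != 0] == 0.2))
  expect_equal(unname(Matrix::colSums(S)), rep(1, 20))

  # two single-node networks: no neighbors, so self-support keeps columns stochastic
  single <- align_networks(reaction_network(nodes = "x"),
                           reaction_network(nodes = "y"), k = 1)
  S1 <- build_support(single$candidates, reaction_network(nodes = "x"),
                      reaction_network(nodes = "y"))
  expect_equal(as.matrix(S1), matrix(1, 1, 1, dimnames = list("x|y", "x|y")))
})

test_that("score iteration matches an independent recurrence oracle", {
  toy <- toy_instance()
  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  net1c <- h1$levels[[2]]
  net2c <- h2$levels[[2]]
  cands <- candidate_mappings(enumerate_subnetworks(net1c, 1),
                              enumerate_subnetworks(net2c, 1), toy$sim)
  S <- build_support(cands, net1c, net2c)

  # gamma = 0 ignores topology entirely
  expect_equal(unname(iterate_scores(S, cands$homology, gamma = 0)),
               cands$homology / sum(cands$homology))
  # an identity support matrix leaves the homology vector fixed
  I6 <- Matrix::Diagonal(6)
  dimnames(I6) <- list(cands$mapping_id, cands$mapping_id)
  expect_equal(unname(iterate_scores(I6, cands$homology, gamma = 0.7)),
               cands$homology / sum(cands$homology))

  s <- iterate_scores(S, cands$homology, gamma = 0.7)
  expect_equal(sum(s), 1)
  expect_equal(unname(s),
               oracle_iterate(S, cands$homology, gamma = 0.7), tolerance = 1e-5)
  # the doubly-supported supernode mapping dominates all others
  expect_true(s["a+b|a'+b'"] > max(s[names(s) != "a+b|a'+b'"]))
  expect_error(iterate_scores(S, cands$homology, gamma = 1), "gamma")
})

test_that("extraction yields a maximal conflict-free set", {
  cands <- tibble::tibble(
    mapping_id = c("b|x", "b|y", "c|z"),
    left_id = c("b", "b", "c"), right_id = c("x", "y", "z"),
    left_nodes = list("b", "b", "c"), right_nodes = list("x", "y", "z"),
    score = c(0.6, 0.4, 0.3)
  )
  al <- extract_alignment(cands)
  expect_equal(al$mappings$mapping_id, c("b|x", "c|z"))

  disjoint <- cands[c(1, 3), ]
  expect_equal(nrow(extract_alignment(disjoint)$mappings), 2)

  # maximality: nothing unselected is conflict-free against the selection
  used_l <- unlist(al$mappings$left_nodes)
  used_r <- unlist(al$mappings$right_nodes)
  rest <- cands[!cands$mapping_id %in% al$mappings$mapping_id, ]
  clash <- vapply(seq_len(nrow(rest)), function(i) {
    any(rest$left_nodes[[i]] %in% used_l) || any(rest$right_nodes[[i]] %in% used_r)
  }, logical(1))
  expect_true(all(clash))
})

test_that("greedy extraction recovers the brute-force optimum on small paths", {
  path <- make_path(3)
  al <- align_networks(path, path, k = 1, sim = identity_sim(path$nodes))
  brute <- extract_alignment(al$candidates, method = "exhaustive")
  expect_equal(al$mappings$mapping_id, brute$mappings$mapping_id)
  expect_equal(al$mappings$mapping_id, paste(path$nodes, path$nodes, sep = "|"))

  big <- align_networks(make_path(4), make_path(4), k = 1)  # 16 candidates
  expect_error(extract_alignment(big$candidates, method = "exhaustive"),
               "guarded")
})

test_that("self-alignment under identity similarity is the identity mapping", {
  for (n in 5:6) {
    path <- make_path(n)
    al <- align_networks(path, path, k = 1, sim = identity_sim(path$nodes))
    expect_equal(al$mappings$left_id, al$mappings$right_id)
    expect_equal(nrow(al$mappings), n)
  }
  tree <- reaction_network(data.frame(from = c("a", "a", "b", "b"),
                                      to = c("b", "c", "d", "e")))
  al <- align_networks(tree, tree, k = 1, sim = identity_sim(tree$nodes))
  expect_equal(al$mappings$left_id, al$mappings$right_id)
})

test_that("alignment of empty networks is empty and the toy alignment is sane", {
  empty <- align_networks(reaction_network(), make_path(3), k = 1)
  expect_equal(nrow(empty$mappings), 0)
  expect_equal(empty$support_dim, 0)

  toy <- toy_instance()
  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  al <- align_networks(h1$levels[[2]], h2$levels[[2]], k = 1, sim = toy$sim)
  expect_equal(al$support_dim, 6)
  expect_equal(al$mappings$mapping_id[1], "a+b|a'+b'")
  expect_equal(glance(al)$support_entries, 36)
})
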