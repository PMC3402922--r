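test_that("the planner reproduces the closed-form compression level", {
  oc <- optimal_c(100, 100, 2)
  expect_equal(round(oc$c_real, 2), 2.24)
  expect_equal(oc$c_level, 2L)

  oc2 <- optimal_c(1000, 1000, 3)
  expect_equal(round(oc2$c_real, 2), 3.34)
  expect_equal(oc2$c_level, 3L)

  # the smaller network plays the role of n, so the formula is symmetric
  expect_equal(optimal_c(50, 400, 2), optimal_c(400, 50, 2))
  expect_equal(optimal_c(1, 1, 1)$c_real, 0)
  expect_equal(optimal_c(1, 1, 1)$c_level, 0L)
  expect_error(optimal_c(0, 10, 1), "positive")
})

test_that("the compress decision uses the subnetwork-count ratio at 0.5 inclusively", {
  mk <- function(nk, mk_, nkc, mkc) {
    tibble::tibble(n_k = nk, m_k = mk_, n_k_c = nkc, m_k_c = mkc)
  }
  expect_true(should_compress(mk(20, 20, 10, 10))$compress)   # y = 0.25
  dec <- should_compress(mk(10, 10, 5, 10))                   # y = 0.5 exactly
  expect_equal(dec$ratio, 0.5)
  expect_true(dec$compress)
  expect_false(should_compress(mk(10, 10, 8, 10))$compress)   # y = 0.8
  expect_error(should_compress(mk(0, 10, 5, 5)), "positive")
})

test_that("planner inputs come from actual subnetwork enumeration", {
  toy <- toy_instance()
  pin <- planner_inputs(toy$net1, toy$net2, k = 1, c = 1)
  expect_equal(pin$n_k, 5)
  expect_equal(pin$m_k, 4)
  expect_equal(pin$n_k_c, 3)
  expect_equal(pin$m_k_c, 2)
  expect_equal(pin$alpha_k, 1)
  dec <- should_compress(pin)
  expect_equal(dec$ratio, 6 / 20)
  expect_true(dec$compress)
})

test_that("refining the worked example's supernode mappings recovers the reaction mappings", {
  toy <- toy_instance()
  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  refined <- dplyr::bind_rows(
    refine_mapping("a+b", "a'+b'", h1, h2, level = 1, k = 1, sim = toy$sim),
    refine_mapping("d+e", "c'+d'", h1, h2, level = 1, k = 1, sim = toy$sim)
  )
  expect_equal(nrow(refined), 4)
  expect_setequal(refined$mapping_id, c("a|a'", "b|b'", "d|d'", "e|c'"))
  expect_false("c" %in% unlist(refined$left_members))
})

test_that("refinement base cases pass mappings through unchanged", {
  toy <- toy_instance()
  h1 <- mds_compress(toy$net1, 1)
  h2 <- mds_compress(toy$net2, 1)
  base <- refine_mapping("a", "a'", h1, h2, level = 0, k = 1,
                         sim = toy$sim, score = 0.5)
  expect_equal(base$mapping_id, "a|a'")
  expect_equal(base$score, 0.5)
  # two singleton supernodes refine to their single children
  single <- refine_mapping("c", "c'+d'", h1, h2, level = 1, k = 1, sim = toy$sim)
  expect_equal(single$mapping_id, "c|c'")
})

test_that("the degenerate pipeline (c = 0) equals the base aligner exactly", {
  for (seed in 1:3) {
    n1 <- scale_free_network(15, seed = seed)
    n2 <- scale_free_network(15, seed = seed + 50)
    sm <- random_similarity(n1$nodes, n2$nodes, seed = seed + 100)
    for (k in 1:2) {
      base <- align_networks(n1, n2, k = k, sim = sm)
      fr <- compress_align_refine(n1, n2, c = 0, k = k, sim = sm)
      expect_equal(fr$compressed$mappings, base$mappings)
      expect_equal(fr$final$score, base$mappings$score)
      expect_equal(fr$final$left_members,
                   lapply(base$mappings$left_nodes, sort))
    }
  }
})

test_that("the full pipeline on the worked example maps the merged supernodes first", {
  toy <- toy_instance()
  res <- compress_align_refine(toy$net1, toy$net2, c = 1, k = 1, sim = toy$sim)
  expect_equal(res$compressed$support_dim, 6)
  expect_equal(res$compressed$mappings$mapping_id[1], "a+b|a'+b'")
  expect_true(all(c("a|a'", "b|b'") %in% res$final$mapping_id))
  expect_equal(glance(res)$c, 1)
})

test_that("refined mappings stay inside their supernode blocks and conflict-free", {
  for (seed in 1:3) {
    n1 <- scale_free_network(20, seed = seed)
    n2 <- scale_free_network(20, seed = seed + 10)
    sm <- random_similarity(n1$nodes, n2$nodes, seed = seed + 20)
    for (cc in 1:2) {
      res <- compress_align_refine(n1, n2, c = cc, k = 1, sim = sm)
      # conflict-freedom at reaction level
      expect_equal(anyDuplicated(unlist(res$final$left_members)), 0L)
      expect_equal(anyDuplicated(unlist(res$final$right_members)), 0L)
      # block containment, checked mapping by mapping
      h1 <- res$hierarchies[[1]]
      h2 <- res$hierarchies[[2]]
      for (i in seq_len(nrow(res$compressed$mappings))) {
        cm <- res$compressed$mappings[i, ]
        ref <- refine_mapping(cm$left_nodes[[1]], cm$right_nodes[[1]],
                              h1, h2, level = cc, k = 1, sim = sm)
        expect_true(all(unlist(ref$left_members) %in% cm$left_members[[1]]))
        expect_true(all(unlist(ref$right_members) %in% cm$right_members[[1]]))
      }
    }
  }
})

test_that("aligning identical paths through compression recovers the identity", {
  ids <- letters[1:8]
  path8 <- make_path(8)
  res <- compress_align_refine(path8, path8, c = 1, k = 1,
                               sim = identity_sim(ids))
  expect_equal(nrow(res$final), 8)
  expect_equal(res$final$left_id, res$final$right_id)
})
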