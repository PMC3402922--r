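# SubMAP-style base aligner: subnetwork enumeration, homology scoring,
# support matrix, iterative score combination, conflict-free extraction.
# Operates identically on reaction networks and compressed networks.

subnetwork_id <- function(nodes) paste(sort_ids(nodes), collapse = ",")
mapping_id <- function(left_id, right_id) paste(left_id, right_id, sep = "|")

#' Enumerate connected subnetworks of bounded size
#'
#' All node subsets of size at most `k` whose induced undirected graph is
#' connected, each emitted exactly once in a deterministic order. In a
#' compressed network the "nodes" are supernodes, so a subnetwork of up to
#' `k` supernodes can cover up to `k * 2^c` reactions.
#'
#' @param net A [reaction_network()].
#' @param k Maximum subnetwork size (`>= 1`).
#' @return A tibble with columns `id`, `nodes` (list), `size`, and
#'   `members` (list of level-0 reactions covered).
#' @export
enumerate_subnetworks <- function(net, k) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  check_that(is_count(k, min = 1), "k must be a positive integer")
  nodes <- net$nodes
  nbr <- neighbor_list(net)
  rank <- stats::setNames(seq_along(nodes), nodes)
  acc <- list()
  emit <- function(set) acc[[length(acc) + 1L]] <<- set
  # ESU-style extension: only neighbors ranked above the anchor node are
  # eligible, and each candidate is offered once, so every connected set is
  # reached exactly once
  extend <- function(sub, ext, anchor_rank, seen) {
    emit(sub)
    if (length(sub) == k || !length(ext)) return(invisible())
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      new_nb <- nbr[[w]]
      new_nb <- new_nb[rank[new_nb] > anchor_rank & !(new_nb %in% seen)]
      seen2 <- c(seen, new_nb)
      extend(c(sub, w), c(ext, new_nb), anchor_rank, seen2)
    }
    invisible()
  }
  for (v in nodes) {
    vnb <- nbr[[v]]
    vnb <- vnb[rank[vnb] > rank[v]]
    extend(v, vnb, rank[v], c(v, vnb))
  }
  mem <- node_members(net)
  tibble::tibble(
    id = vapply(acc, subnetwork_id, character(1)),
    nodes = lapply(acc, sort_ids),
    size = lengths(acc),
    members = lapply(acc, function(s) sort_ids(unlist(mem[s], use.names = FALSE)))
  )
}

#' Candidate one-to-many mappings between two subnetwork sets
#'
#' Pairs one subnetwork from each side subject to the one-to-many
#' constraint `min(|left|, |right|) = 1`. The homology of a pair is the
#' aggregate of reaction-level similarities over the cross product of the
#' two member sets (arithmetic mean by default; `"max"` optionally).
#'
#' @param subs1,subs2 Subnetwork tibbles from [enumerate_subnetworks()].
#' @param sim Similarity: `"uniform"` or a matrix / long table accepted by
#'   [similarity_table()].
#' @param aggregate `"mean"` (conservative default) or `"max"`.
#' @return A tibble of candidate mappings with columns `mapping_id`,
#'   `left_id`, `right_id`, `left_nodes`, `right_nodes`, `left_members`,
#'   `right_members`, `left_size`, `right_size`, `homology`.
#' @export
candidate_mappings <- function(subs1, subs2, sim = "uniform",
                               aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else max
  sim <- as_similarity(sim)
  ok <- outer(subs1$size == 1L, subs2$size == 1L, `|`)
  idx <- which(ok, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  if (!nrow(idx)) {
    return(tibble::tibble(mapping_id = character(), left_id = character(),
                          right_id = character(), left_nodes = list(),
                          right_nodes = list(), left_members = list(),
                          right_members = list(), left_size = integer(),
                          right_size = integer(), homology = numeric()))
  }
  all_m1 <- sort_ids(unlist(subs1$members, use.names = FALSE))
  all_m2 <- sort_ids(unlist(subs2$members, use.names = FALSE))
  simm <- sim_values(sim, all_m1, all_m2)
  hom <- vapply(seq_len(nrow(idx)), function(r) {
    agg(simm[subs1$members[[idx[r, 1]]], subs2$members[[idx[r, 2]]]])
  }, numeric(1))
  left_id <- subs1$id[idx[, 1]]
  right_id <- subs2$id[idx[, 2]]
  tibble::tibble(
    mapping_id = mapping_id(left_id, right_id),
    left_id = left_id, right_id = right_id,
    left_nodes = subs1$nodes[idx[, 1]],
    right_nodes = subs2$nodes[idx[, 2]],
    left_members = subs1$members[idx[, 1]],
    right_members = subs2$members[idx[, 2]],
    left_size = subs1$size[idx[, 1]],
    right_size = subs2$size[idx[, 2]],
    homology = hom
  )
}

# forward / backward neighbor node sets of each distinct subnetwork
subnetwork_neighbors <- function(sub_nodes, net) {
  ef <- net$edges[, 1]
  et <- net$edges[, 2]
  lapply(sub_nodes, function(s) {
    list(fwd = sort_ids(setdiff(et[ef %in% s], s)),
         bwd = sort_ids(setdiff(ef[et %in% s], s)))
  })
}

#' Topological support matrix over candidate mappings
#'
#' A mapping `M = (R, R')` supports a mapping `N = (S, S')` when `S`
#' touches a forward neighbor of `R` and `S'` a forward neighbor of `R'`,
#' or symmetrically for backward neighbors; `M` splits one unit of support
#' equally among the `d` mappings it supports, so every column with at
#' least one supported mapping sums to one. A column with none gets
#' self-support 1, keeping the matrix column-stochastic.
#'
#' @param cands Candidate tibble from [candidate_mappings()].
#' @param net1,net2 The two networks being aligned.
#' @return A sparse column-stochastic matrix (`Matrix::dgCMatrix`) with
#'   mapping identifiers as dimnames.
#' @export
build_support <- function(cands, net1, net2) {
  check_that(nrow(cands) > 0, "candidate list must be nonempty")
  n <- nrow(cands)
  # membership: node -> candidate indices containing it on that side
  side_index <- function(node_lists) {
    split(rep(seq_len(n), lengths(node_lists)),
          unlist(node_lists, use.names = FALSE))
  }
  left_index <- side_index(cands$left_nodes)
  right_index <- side_index(cands$right_nodes)
  nb1 <- subnetwork_neighbors(cands$left_nodes, net1)
  nb2 <- subnetwork_neighbors(cands$right_nodes, net2)
  cand_hits <- function(index, nodes) {
    if (!length(nodes)) return(integer())
    unique(unlist(index[nodes], use.names = FALSE))
  }
  rows <- vector("list", n)
  vals <- vector("list", n)
  for (i in seq_len(n)) {
    fwd <- intersect(cand_hits(left_index, nb1[[i]]$fwd),
                     cand_hits(right_index, nb2[[i]]$fwd))
    bwd <- intersect(cand_hits(left_index, nb1[[i]]$bwd),
                     cand_hits(right_index, nb2[[i]]$bwd))
    supported <- sort(unique(c(fwd, bwd)))
    if (length(supported)) {
      rows[[i]] <- supported
      vals[[i]] <- rep(1 / length(supported), length(supported))
    } else {
      rows[[i]] <- i
      vals[[i]] <- 1
    }
  }
  Matrix::sparseMatrix(
    i = unlist(rows), j = rep(seq_len(n), lengths(rows)), x = unlist(vals),
    dims = c(n, n), dimnames = list(cands$mapping_id, cands$mapping_id)
  )
}

#' Iterative combination of homology and topological support
#'
#' Iterates `s <- gamma * S s + (1 - gamma) * h` from `s = h` until the
#' max-norm change drops below `tol` or `max_iter` is reached, then
#' renormalizes to sum one. With a column-stochastic `S` the vector sum is
#' preserved at every iteration, so the fixed point balances pairwise
#' homology against network topology.
#'
#' @param S Support matrix from [build_support()].
#' @param h Homology vector (renormalized internally to sum 1).
#' @param gamma Topology weight in `[0, 1)`.
#' @param tol Convergence tolerance (max-norm).
#' @param max_iter Iteration cap.
#' @return Named numeric score vector summing to one.
#' @export
iterate_scores <- function(S, h, gamma = 0.7, tol = 1e-6, max_iter = 100L) {
  check_that(is.numeric(gamma) && gamma >= 0 && gamma < 1,
             "gamma must lie in [0, 1)")
  check_that(length(h) == nrow(S), "h must match the support matrix dimension")
  check_that(all(is.finite(h)) && all(h >= 0) && sum(h) > 0,
             "h must be non-negative, finite, and not all zero")
  h <- h / sum(h)
  s <- h
  for (it in seq_len(max_iter)) {
    s_new <- as.vector(gamma * (S %*% s) + (1 - gamma) * h)
    check_that(all(is.finite(s_new)), "score iteration produced non-finite values")
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) break
  }
  s <- s / sum(s)
  names(s) <- rownames(S)
  s
}

conflict_free <- function(cands, chosen) {
  used1 <- unlist(cands$left_nodes[chosen], use.names = FALSE)
  used2 <- unlist(cands$right_nodes[chosen], use.names = FALSE)
  !anyDuplicated(used1) && !anyDuplicated(used2)
}

extract_greedy <- function(cands) {
  ord <- order(-cands$score, cands$mapping_id, method = "radix")
  used1 <- character()
  used2 <- character()
  take <- integer()
  for (i in ord) {
    l <- cands$left_nodes[[i]]
    r <- cands$right_nodes[[i]]
    if (!any(l %in% used1) && !any(r %in% used2)) {
      take <- c(take, i)
      used1 <- c(used1, l)
      used2 <- c(used2, r)
    }
  }
  sort(take)
}

extract_exhaustive <- function(cands) {
  n <- nrow(cands)
  check_that(n <= 12L, "exhaustive extraction is guarded to 12 candidates")
  best <- integer()
  best_score <- -Inf
  recurse <- function(i, chosen, used1, used2, total) {
    if (i > n) {
      if (total > best_score + 1e-12) {
        best <<- chosen
        best_score <<- total
      }
      return(invisible())
    }
    l <- cands$left_nodes[[i]]
    r <- cands$right_nodes[[i]]
    if (!any(l %in% used1) && !any(r %in% used2)) {
      recurse(i + 1L, c(chosen, i), c(used1, l), c(used2, r),
              total + cands$score[i])
    }
    recurse(i + 1L, chosen, used1, used2, total)
    invisible()
  }
  recurse(1L, integer(), character(), character(), 0)
  sort(best)
}

#' Extract a conflict-free alignment from scored candidates
#'
#' Selects candidate mappings in descending score order (ties broken by
#' mapping identifier) such that no node of either network appears in more
#' than one selected mapping; the result is a maximal conflict-free set.
#' `method = "exhaustive"` instead maximizes total score by brute force
#' (guarded to 12 candidates) and serves as an oracle for the greedy rule.
#'
#' @param cands Candidate tibble carrying a `score` column.
#' @param method `"greedy"` or `"exhaustive"`.
#' @return A `network_alignment` object; its `mappings` tibble holds the
#'   selected rows.
#' @export
extract_alignment <- function(cands, method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  check_that("score" %in% names(cands), "candidates must carry a score column")
  take <- if (nrow(cands)) {
    switch(method, greedy = extract_greedy(cands),
           exhaustive = extract_exhaustive(cands))
  } else {
    integer()
  }
  new_network_alignment(mappings = cands[take, , drop = FALSE],
                        candidates = cands)
}

new_network_alignment <- function(mappings, candidates, params = list()) {
  structure(
    list(mappings = mappings, candidates = candidates,
         support_dim = nrow(candidates), params = params),
    class = "network_alignment"
  )
}

#' @export
print.network_alignment <- function(x, ...) {
  cat(sprintf("<network_alignment> %d mapping(s) from %d candidates (support %dx%d)\n",
              nrow(x$mappings), x$support_dim, x$support_dim, x$support_dim))
  if (nrow(x$mappings)) {
    print(utils::head(x$mappings[, c("mapping_id", "homology", "score")], 10L))
  }
  invisible(x)
}

#' Align two networks with the SubMAP-style base aligner
#'
#' Enumerates connected subnetworks of size at most `k` on both sides,
#' forms all one-to-many candidate mappings, scores them by combining
#' reaction homology with topological support ([build_support()],
#' [iterate_scores()]), and extracts a conflict-free alignment. Works
#' identically in the original and the compressed domain.
#'
#' @param net1,net2 [reaction_network()] objects (same level).
#' @param k Maximum subnetwork size.
#' @param sim Similarity (see [candidate_mappings()]).
#' @param gamma,tol,max_iter Score-iteration parameters ([iterate_scores()]).
#' @param aggregate Homology aggregation over member pairs.
#' @param method Extraction rule ([extract_alignment()]).
#' @return A `network_alignment`: selected `mappings`, the full scored
#'   `candidates` table, and `support_dim` (the support-matrix side).
#' @examples
#' p <- reaction_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' align_networks(p, p, k = 1)$mappings
#' @export
align_networks <- function(net1, net2, k = 1L, sim = "uniform", gamma = 0.7,
                           tol = 1e-6, max_iter = 100L,
                           aggregate = c("mean", "max"),
                           method = c("greedy", "exhaustive")) {
  check_that(inherits(net1, "reaction_network") &&
               inherits(net2, "reaction_network"),
             "net1 and net2 must be reaction_network objects")
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  params <- list(k = as.integer(k), gamma = gamma, tol = tol,
                 max_iter = max_iter, aggregate = aggregate, method = method)
  if (!n_nodes(net1) || !n_nodes(net2)) {
    empty <- candidate_mappings(enumerate_subnetworks(reaction_network(), k)[0, ],
                                enumerate_subnetworks(reaction_network(), k)[0, ])
    empty$score <- numeric()
    return(new_network_alignment(empty, empty, params))
  }
  subs1 <- enumerate_subnetworks(net1, k)
  subs2 <- enumerate_subnetworks(net2, k)
  cands <- candidate_mappings(subs1, subs2, sim, aggregate)
  S <- build_support(cands, net1, net2)
  h <- cands$homology
  if (sum(h) == 0) h <- rep(1, length(h))  # no homology signal: uniform prior
  cands$score <- unname(iterate_scores(S, h, gamma, tol, max_iter))
  out <- extract_alignment(cands, method)
  out$params <- params
  out
}
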