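# Optimal-compression oracles and the MDS optimality bounds.
#
# One level of optimal compression equals a maximum cardinality matching in
# the underlying undirected simple graph: each non-compressed node may merge
# with at most one other per level, merges must follow edges, and every
# merge removes one node. Two independent exact routes are provided (a
# bitmask dynamic program and exhaustive matching enumeration) so each can
# serve as an oracle for the other on small instances.

# unique undirected edges as an index matrix over net$nodes
undirected_pairs <- function(net) {
  if (!n_edges(net)) return(matrix(integer(), ncol = 2L))
  i <- match(net$edges[, 1], net$nodes)
  j <- match(net$edges[, 2], net$nodes)
  m <- cbind(pmin(i, j), pmax(i, j))
  unique(m)
}

# adjacency bitmasks (nodes indexed 1..n, bit k-1 for node k)
adjacency_bits <- function(pairs, n) {
  adj <- integer(n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  adj
}

max_matching_dp <- function(pairs, n) {
  if (!nrow(pairs)) return(0L)
  check_that(n <= 20L, "dynamic-program matching is guarded to 20 nodes")
  adj <- adjacency_bits(pairs, n)
  size <- bitwShiftL(1L, n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  dp <- integer(size)  # dp[mask + 1] = max matching within node set `mask`
  for (mask in seq_len(size - 1L)) {
    low <- bitwAnd(mask, -mask)           # lowest set bit
    i <- match(low, bits)
    rest <- bitwAnd(mask, bitwNot(low))
    best <- dp[rest + 1L]                 # leave node i unmatched
    cand <- bitwAnd(adj[i], rest)
    while (cand != 0L) {
      lowj <- bitwAnd(cand, -cand)
      best <- max(best, 1L + dp[bitwAnd(rest, bitwNot(lowj)) + 1L])
      cand <- bitwAnd(cand, bitwNot(lowj))
    }
    dp[mask + 1L] <- best
  }
  dp[size]
}

# enumerate all matchings (as lists of pair-row indices); calls `fun` on each
for_each_matching <- function(pairs, fun) {
  n_pair <- nrow(pairs)
  recurse <- function(start, used, chosen) {
    fun(chosen)
    if (start > n_pair) return(invisible())
    for (r in start:n_pair) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used[i] && !used[j]) {
        used[i] <- used[j] <- TRUE
        recurse(r + 1L, used, c(chosen, r))
        used[i] <- used[j] <- FALSE
      }
    }
    invisible()
  }
  if (n_pair) {
    recurse(1L, logical(max(pairs)), integer())
  } else {
    fun(integer())
  }
  invisible()
}

max_matching_exhaustive <- function(pairs, n) {
  check_that(n <= 12L, "exhaustive matching enumeration is guarded to 12 nodes")
  best <- 0L
  for_each_matching(pairs, function(chosen) {
    if (length(chosen) > best) best <<- length(chosen)
  })
  best
}

#' Exact one-level optimal compression
#'
#' The largest number of merges achievable in a single compression level,
#' i.e. the size of a maximum cardinality matching in the underlying
#' undirected simple graph.
#'
#' @param net A [reaction_network()].
#' @param method `"dp"` (bitmask dynamic program, up to 20 nodes) or
#'   `"exhaustive"` (matching enumeration, up to 12 nodes). The two routes
#'   are independent implementations and must agree.
#' @return Integer number of merges.
#' @export
opt_one_level <- function(net, method = c("dp", "exhaustive")) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  method <- match.arg(method)
  pairs <- undirected_pairs(net)
  n <- n_nodes(net)
  switch(method,
         dp = max_matching_dp(pairs, n),
         exhaustive = max_matching_exhaustive(pairs, n))
}

# contract an arbitrary matching (rows of undirected_pairs) into the
# coarsened simple network, mirroring the supernode edge rules
contract_matching <- function(net, pair_rows, pairs = undirected_pairs(net)) {
  parent <- stats::setNames(net$nodes, net$nodes)
  for (r in pair_rows) {
    ch <- sort_ids(net$nodes[pairs[r, ]])
    parent[ch] <- paste(ch, collapse = "+")
  }
  new_nodes <- sort_ids(unname(parent))
  if (n_edges(net)) {
    pf <- unname(parent[net$edges[, 1]])
    pt <- unname(parent[net$edges[, 2]])
    ext <- unique(cbind(pf, pt)[pf != pt, , drop = FALSE])
  } else {
    ext <- matrix(character(), ncol = 2L)
  }
  reaction_network(ext, nodes = new_nodes, level = net$level + 1L)
}

#' Exact multi-level optimal compression
#'
#' Maximum total number of merges over `levels` compression levels, found
#' by exhaustive search over per-level matchings (a maximum matching at one
#' level is not necessarily the best first move across several levels).
#' Exponential; guarded to networks of at most 10 nodes.
#'
#' @inheritParams opt_one_level
#' @param levels Number of compression levels.
#' @return Integer total number of merges.
#' @export
opt_multi_level <- function(net, levels) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  check_that(is_count(levels), "levels must be a non-negative integer")
  check_that(n_nodes(net) <= 10L,
             "opt_multi_level is guarded to networks of at most 10 nodes")
  opt_multi_pairs(undirected_pairs(net), n_nodes(net), as.integer(levels))
}

# contract a matching on the integer pair representation
contract_pairs <- function(pairs, n, chosen) {
  parent <- seq_len(n)
  for (r in chosen) parent[pairs[r, 2]] <- pairs[r, 1]
  relab <- match(parent, sort(unique(parent)))
  i <- relab[pairs[, 1]]
  j <- relab[pairs[, 2]]
  keep <- i != j
  list(pairs = unique(cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))),
       n = max(relab))
}

opt_multi_pairs <- function(pairs, n, levels) {
  if (levels == 0L || !nrow(pairs)) return(0L)
  if (levels == 1L) return(max_matching_dp(pairs, n))
  best <- 0L
  for_each_matching(pairs, function(chosen) {
    ctr <- contract_pairs(pairs, n, chosen)
    total <- length(chosen) + opt_multi_pairs(ctr$pairs, ctr$n, levels - 1L)
    if (total > best) best <<- total
  })
  best
}

#' Level-wise optimal merge count along an MDS trajectory
#'
#' Sum over levels of the exact one-level optimum (maximum matching) of
#' each network the MDS compression actually produced. This is the
#' quantity the `s + MDS` and `2 * MDS` upper bounds provably dominate:
#' the bounds' accounting is per level, comparing the optimal compression
#' of each intermediate network with the MDS steps taken on it. A fully
#' free multi-level trajectory ([opt_multi_level()]) can exceed these
#' bounds, because a level-wise optimal merge (even one involving a
#' degree-one node) may close off better merges at later levels.
#'
#' @param h A [compression_hierarchy] from [mds_compress()].
#' @return Integer total of per-level optimal merge counts.
#' @export
opt_levelwise <- function(h) {
  check_that(inherits(h, "compression_hierarchy"), "h must be a compression_hierarchy")
  lv <- h$levels
  if (length(lv) < 2L) return(0L)
  sum(vapply(lv[-length(lv)], opt_one_level, integer(1)))
}

#' Optimality report for an MDS hierarchy
#'
#' Summarizes how far an MDS compression can be from optimal: the realized
#' merge count, the number `s` of merge steps taken while no degree-one
#' node was available, the two upper bounds on the optimal merge count
#' (`2 * MDS` and `s + MDS`), their minimum, and the implied lower bound on
#' the optimally compressed size.
#'
#' @param h A [compression_hierarchy] from [mds_compress()].
#' @param exact_opt Optional exact optimal merge count (e.g. from
#'   [opt_multi_level()]); when supplied it is verified to lie between
#'   `mds_steps` and `combined_bound`.
#' @return A one-row tibble.
#' @export
optimality_report <- function(h, exact_opt = NULL) {
  validate_hierarchy(h)
  n <- n_nodes(h$levels[[1]])
  mds_steps <- nrow(h$steps)
  s <- sum(!h$steps$degree_one_available)
  bound_2mds <- 2L * mds_steps
  bound_s_plus <- s + mds_steps
  combined <- min(bound_2mds, bound_s_plus)
  if (!is.null(exact_opt)) {
    check_that(exact_opt >= mds_steps && exact_opt <= combined,
               "exact optimum %d outside [MDS = %d, bound = %d]",
               exact_opt, mds_steps, combined)
  }
  tibble::tibble(
    n = n, mds_steps = mds_steps, s = s,
    bound_2mds = bound_2mds, bound_s_plus = bound_s_plus,
    combined_bound = combined,
    n_mds = n - mds_steps,
    n_opt_lower = n - combined,
    opt_steps = if (is.null(exact_opt)) NA_integer_ else as.integer(exact_opt)
  )
}

#' Size ratio of MDS-compressed to optimally compressed network
#'
#' `n_MDS / n_OPT`, where `n_MDS = n - mds_steps` and
#' `n_OPT = n - exact_opt_steps`. After one compression level this ratio is
#' at most 1.5.
#'
#' @inheritParams optimality_report
#' @param exact_opt_steps Exact optimal merge count.
#' @return A real number `>= 1`.
#' @export
size_ratio <- function(h, exact_opt_steps) {
  rep_ <- optimality_report(h, exact_opt = exact_opt_steps)
  n_opt <- rep_$n - exact_opt_steps
  check_that(n_opt > 0, "optimal compressed size is zero; ratio undefined")
  rep_$n_mds / n_opt
}

#' Canonical enumeration of small connected directed test graphs
#'
#' Generates every labeled connected undirected graph on `n` nodes
#' (identifiers `a`, `b`, ...), orienting each edge from the smaller to the
#' larger identifier. This is the package's canonical family of small
#' directed graphs for exhaustive optimality checks; minimum-degree
#' selection and matching depend only on the underlying incidence
#' structure, so the canonical orientation loses no generality for those
#' checks.
#'
#' @param n Number of nodes (2 to 6).
#' @return A list of level-0 [reaction_network()] objects
#'   (1, 4, 38, 728 and 26704 graphs for n = 2..6).
#' @export
enumerate_connected_graphs <- function(n) {
  check_that(is_count(n, min = 2) && n <= 6, "n must be between 2 and 6")
  ids <- letters[seq_len(n)]
  prs <- t(utils::combn(n, 2L))
  np <- nrow(prs)
  bit <- bitwShiftL(1L, seq_len(np) - 1L)
  out <- vector("list", 2^np)
  found <- 0L
  for (mask in seq_len(2^np - 1L)) {
    sel <- which(bitwAnd(mask, bit) != 0L)
    # connectivity over all n nodes via union-find
    root <- seq_len(n)
    find <- function(i) { while (root[i] != i) i <- root[i]; i }
    for (r in sel) {
      a <- find(prs[r, 1]); b <- find(prs[r, 2])
      if (a != b) root[a] <- b
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L) {
      em <- cbind(ids[prs[sel, 1]], ids[prs[sel, 2]])
      colnames(em) <- c("from", "to")
      found <- found + 1L
      out[[found]] <- new_reaction_network(ids, em, 0L, NULL)
    }
  }
  out[seq_len(found)]
}
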