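#' Active degree of a node during a compression level
#'
#' During a compression level, nodes already absorbed into a supernode are
#' "compressed"; the degree that drives the minimum-degree selection counts
#' only edges whose other endpoint is still non-compressed. The count is
#' `indeg + outdeg`, so a reciprocal pair `a <-> b` contributes two to each
#' endpoint.
#'
#' @param net A [reaction_network()].
#' @param node Node identifier.
#' @param compressed Character vector of nodes already compressed this level.
#' @return Non-negative integer.
#' @export
active_degree <- function(net, node, compressed = character()) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  if (!node %in% net$nodes) stop_validation("node '%s' not in network", node)
  check_that(all(compressed %in% net$nodes), "compressed must be a subset of nodes")
  inc <- incidence_list(net)[[node]]
  if (is.null(inc)) return(0L)
  sum(!(inc %in% compressed))
}

#' Stepwise MDS compression state
#'
#' `mds_state()` initializes the intermediate state for one level of
#' minimum degree selection (MDS) compression of `net`; `mds_step()`
#' performs a single merge (one supernode created, node count down by one),
#' and `mds_finish()` assembles the level-`x+1` network together with its
#' supernode table and step log.
#'
#' @param net A [reaction_network()].
#' @return `mds_state()` returns an `mds_state` object.
#' @export
mds_state <- function(net) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  structure(
    list(net = net, inc = incidence_list(net),
         compressed = character(), merges = list(), log = list()),
    class = "mds_state"
  )
}

state_active_degrees <- function(state) {
  open <- setdiff(state$net$nodes, state$compressed)
  comp <- state$compressed
  vapply(state$inc[open], function(others) {
    if (is.null(others)) 0L else sum(!(others %in% comp))
  }, integer(1))
}

#' @rdname mds_state
#' @param state An `mds_state`.
#' @param choose_node,choose_neighbor Selectors used when several nodes have
#'   the minimum positive degree (resp. several neighbors are available).
#'   Each receives a character vector of candidates and must return one of
#'   them. The defaults take the first identifier in C-locale order, which
#'   makes the algorithm deterministic.
#' @export
mds_step <- function(state, choose_node = first_id, choose_neighbor = first_id) {
  check_that(inherits(state, "mds_state"), "state must come from mds_state()")
  deg <- state_active_degrees(state)
  pos <- deg[deg > 0L]
  check_that(length(pos) > 0L,
             "no non-compressed node with positive degree remains")
  dmin <- min(pos)
  v_a <- choose_node(sort_ids(names(pos)[pos == dmin]))
  others <- state$inc[[v_a]]
  nbrs <- sort_ids(others[!(others %in% state$compressed)])
  v_b <- choose_neighbor(nbrs)
  children <- sort_ids(c(v_a, v_b))
  sid <- paste(children, collapse = "+")
  state$compressed <- c(state$compressed, v_a, v_b)
  state$merges <- c(state$merges, list(children))
  state$log <- c(state$log, list(list(
    v_a = v_a, v_b = v_b, supernode = sid,
    degree_one_available = dmin == 1L
  )))
  state
}

#' @rdname mds_state
#' @export
mds_finish <- function(state) {
  check_that(inherits(state, "mds_state"), "state must come from mds_state()")
  net <- state$net
  new_level <- net$level + 1L
  parent <- stats::setNames(net$nodes, net$nodes)
  for (pair in state$merges) {
    parent[pair] <- paste(pair, collapse = "+")
  }
  mem_prev <- node_members(net)

  new_nodes <- sort_ids(unname(parent))
  children <- split(names(parent), parent)[new_nodes]
  members <- lapply(children, function(ch) {
    sort_ids(unlist(mem_prev[ch], use.names = FALSE))
  })

  if (n_edges(net)) {
    pf <- unname(parent[net$edges[, 1]])
    pt <- unname(parent[net$edges[, 2]])
    internal <- pf == pt
    ext <- unique(cbind(pf[internal == FALSE], pt[internal == FALSE]))
  } else {
    internal <- logical(0)
    ext <- matrix(character(), ncol = 2L)
  }
  internal_edges <- lapply(new_nodes, function(id) {
    if (n_edges(net)) {
      keep <- internal & unname(parent[net$edges[, 1]]) == id
      m <- net$edges[keep, , drop = FALSE]
    } else {
      m <- matrix(character(), ncol = 2L)
    }
    colnames(m) <- c("from", "to")
    m
  })

  out_net <- reaction_network(ext, nodes = new_nodes, level = new_level,
                              members = stats::setNames(members, new_nodes))
  sup <- tibble::new_tibble(list(
    level = rep(new_level, length(new_nodes)),
    id = new_nodes,
    children = unname(children),
    members = unname(members),
    internal_edges = internal_edges
  ), nrow = length(new_nodes))
  nlog <- length(state$log)
  steps <- if (nlog) {
    tibble::new_tibble(list(
      level = rep(new_level, nlog),
      step = seq_len(nlog),
      v_a = vapply(state$log, `[[`, character(1), "v_a"),
      v_b = vapply(state$log, `[[`, character(1), "v_b"),
      supernode = vapply(state$log, `[[`, character(1), "supernode"),
      degree_one_available = vapply(state$log, `[[`, logical(1),
                                    "degree_one_available")
    ), nrow = nlog)
  } else {
    empty_step_table()
  }
  list(network = out_net, supernodes = sup, steps = steps)
}

#' One level of MDS compression
#'
#' Repeatedly merges a minimum-positive-degree non-compressed node with one
#' of its non-compressed neighbors until no two non-compressed nodes remain
#' adjacent, then rebuilds the coarsened network. Supernodes at the new
#' level hold two nodes of the input; carried-over singletons hold one.
#'
#' @inheritParams mds_state
#' @inheritParams mds_step
#' @return A list with `network` (the level-`x+1` [reaction_network()]),
#'   `supernodes`, and `steps` (tibbles as stored in a
#'   [compression_hierarchy]).
#' @export
mds_level <- function(net, choose_node = first_id, choose_neighbor = first_id) {
  state <- mds_state(net)
  repeat {
    deg <- state_active_degrees(state)
    if (!any(deg > 0L)) break
    state <- mds_step(state, choose_node, choose_neighbor)
  }
  mds_finish(state)
}

#' Multilevel MDS compression
#'
#' Applies [mds_level()] `levels` times, treating each coarsened network as
#' a fresh non-compressed network, and records the whole hierarchy. After
#' level `x` every node holds between 1 and `2^x` reactions.
#'
#' @inheritParams mds_state
#' @param levels Number of compression levels `c >= 0`.
#' @inheritParams mds_step
#' @return A [compression_hierarchy] with `levels + 1` networks.
#' @examples
#' net <- reaction_network(data.frame(from = c("a", "b", "b", "d"),
#'                                    to   = c("b", "c", "d", "e")))
#' h <- mds_compress(net, 1)
#' n_nodes(h$levels[[2]])
#' @export
mds_compress <- function(net, levels, choose_node = first_id,
                         choose_neighbor = first_id) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  check_that(is_count(levels), "levels must be a non-negative integer")
  nets <- list(net)
  sup <- empty_supernode_table()
  steps <- empty_step_table()
  if (levels > 0) {
    for (x in seq_len(levels)) {
      lv <- mds_level(nets[[x]], choose_node, choose_neighbor)
      nets[[x + 1L]] <- lv$network
      sup <- dplyr::bind_rows(sup, lv$supernodes)
      steps <- dplyr::bind_rows(steps, lv$steps)
    }
  }
  h <- new_compression_hierarchy(nets, sup, steps)
  validate_hierarchy(h)
  h
}

#' Randomized MDS compression
#'
#' Identical to [mds_compress()] except that, at each step, the node to
#' compress is drawn uniformly from the set of minimum-positive-degree
#' nodes using a seeded generator. The same seed always reproduces the
#' same hierarchy. Used to probe the stability of the deterministic
#' tie-break rule.
#'
#' @inheritParams mds_compress
#' @param seed Integer seed.
#' @return A [compression_hierarchy].
#' @export
mds_compress_randomized <- function(net, levels, seed) {
  check_that(is_count(seed), "seed must be a non-negative integer")
  pick_random <- function(ids) ids[sample.int(length(ids), 1L)]
  withr::with_seed(as.integer(seed), {
    mds_compress(net, levels, choose_node = pick_random)
  })
}

#' Decompress a block of nodes by one level
#'
#' Given nodes of level `x`, returns the level-`x-1` network induced by
#' their children: the edges internal to each supernode plus the
#' level-`x-1` edges running between children of different listed nodes.
#' Used by the refinement phase to turn a supernode mapping back into a
#' small alignment instance.
#'
#' @param h A [compression_hierarchy].
#' @param level Level of the listed nodes (`>= 1`).
#' @param node_ids Character vector of node identifiers at `level`.
#' @return A [reaction_network()] at `level - 1` carrying member sets.
#' @export
decompress_block <- function(h, level, node_ids) {
  check_that(inherits(h, "compression_hierarchy"), "h must be a compression_hierarchy")
  check_that(is_count(level, min = 1) && level <= max_level(h),
             "level must be between 1 and max_level(h)")
  net <- h$levels[[level + 1L]]
  unknown <- setdiff(node_ids, net$nodes)
  if (length(unknown)) {
    stop_validation("node '%s' does not exist at level %d", unknown[1], level)
  }
  rows <- h$supernodes[h$supernodes$level == level &
                         h$supernodes$id %in% node_ids, ]
  children <- sort_ids(unlist(rows$children, use.names = FALSE))
  prev <- h$levels[[level]]
  keep <- prev$edges[, 1] %in% children & prev$edges[, 2] %in% children
  mem_prev <- node_members(prev)[children]
  reaction_network(prev$edges[keep, , drop = FALSE], nodes = children,
                   level = prev$level, members = mem_prev)
}
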