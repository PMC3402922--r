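# Seeded generators for test instances: scale-free directed networks and
# the small worked-example pair used throughout the documentation.

#' Seeded scale-free directed network
#'
#' Grows a connected network by preferential attachment (each new node
#' attaches to an existing node with probability proportional to degree
#' raised to `attachment_exponent`) and then orients every edge at random
#' with probability 1/2 per direction. The resulting out-degree
#' distribution is heavy-tailed, emulating the few-hubs/many-leaves shape
#' of reaction-based metabolic networks. A pure function of its seed.
#'
#' @param n Number of nodes (`>= 2`).
#' @param attachment_exponent Preferential-attachment power (1 = linear).
#' @param seed Integer seed.
#' @return A level-0 [reaction_network()] with identifiers `r001`, ...
#' @export
scale_free_network <- function(n, attachment_exponent = 1, seed) {
  check_that(is_count(n, min = 2), "n must be an integer >= 2")
  check_that(is_count(seed), "seed must be a non-negative integer")
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf("r%0*d", width, seq_len(n))
  withr::with_seed(as.integer(seed), {
    g <- igraph::sample_pa(n, power = attachment_exponent, m = 1,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- stats::runif(nrow(el)) < 0.5
    from <- ifelse(flip, el[, 2], el[, 1])
    to <- ifelse(flip, el[, 1], el[, 2])
    reaction_network(cbind(ids[from], ids[to]), nodes = ids)
  })
}

#' Worked-example network pair
#'
#' Two small hypothetical metabolic networks of 5 and 4 reactions used
#' throughout the documentation and tests:
#' `P = {a->b, b->c, b->d, d->e}` and
#' `P' = {a'->b', b'->c', b'->d', c'->d'}`. One level of MDS compression
#' reduces them to 3 and 2 supernodes, shrinking the support matrix needed
#' for alignment from 20x20 to 6x6 at `k = 1`.
#'
#' The bundled similarity is a fixture convention, not a biochemical
#' score: 1.0 for same-letter pairs (`a` vs `a'`), 0.1 otherwise, chosen
#' so that letter-matched one-to-one alignment is the unique optimum in
#' the original domain.
#'
#' @return A list with `net1`, `net2` ([reaction_network()] objects) and
#'   `sim` (a similarity matrix, see [similarity_table()]).
#' @examples
#' toy <- toy_instance()
#' n_nodes(toy$net1)  # 5
#' @export
toy_instance <- function() {
  net1 <- reaction_network(data.frame(
    from = c("a", "b", "b", "d"),
    to = c("b", "c", "d", "e")
  ))
  net2 <- reaction_network(data.frame(
    from = c("a'", "b'", "b'", "c'"),
    to = c("b'", "c'", "d'", "d'")
  ))
  sim <- outer(net1$nodes, net2$nodes,
               function(x, y) ifelse(x == substr(y, 1, 1), 1.0, 0.1))
  dimnames(sim) <- list(net1$nodes, net2$nodes)
  list(net1 = net1, net2 = net2, sim = sim)
}
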