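#' Reaction networks
#'
#' A `reaction_network` is a simple directed graph over string identifiers.
#' At compression level 0 the identifiers are reactions of a metabolic
#' network, with an edge `r_i -> r_j` whenever an output compound of `r_i`
#' is an input of `r_j`. At level `x > 0` the identifiers name supernodes,
#' each containing between 1 and `2^x` reactions.
#'
#' @param edges A data frame (first two columns used as from/to), a
#'   two-column character matrix, or `NULL` for an edgeless network.
#'   Duplicate edges are collapsed; self-loops are rejected.
#' @param nodes Optional additional (isolated) node identifiers.
#' @param level Non-negative integer compression level.
#' @param members Optional named list mapping each node to its set of
#'   level-0 reaction identifiers. `NULL` means each node is its own
#'   member set (the level-0 convention).
#' @return A `reaction_network` object.
#' @examples
#' net <- reaction_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' n_nodes(net)
#' @export
reaction_network <- function(edges = NULL, nodes = character(), level = 0L,
                             members = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else if (is.matrix(edges)) {
    check_that(ncol(edges) >= 2L, "edge matrix needs two columns")
    em <- edges[, 1:2, drop = FALSE]
    mode(em) <- "character"
  } else {
    edges <- as.data.frame(edges)
    check_that(ncol(edges) >= 2L, "edge table needs two columns")
    em <- cbind(as.character(edges[[1]]), as.character(edges[[2]]))
  }
  if (nrow(em)) {
    bad <- em[, 1] == em[, 2]
    if (any(bad)) {
      stop_validation("self-loop on node '%s' is not allowed", em[which(bad)[1], 1])
    }
    em <- unique(em)
    em <- em[order_ids(em[, 1], em[, 2]), , drop = FALSE]
  }
  colnames(em) <- c("from", "to")
  nodes <- sort_ids(c(as.character(nodes), as.vector(em)))
  check_that(is_count(level), "level must be a non-negative integer")
  if (!is.null(members)) {
    check_that(setequal(names(members), nodes),
               "members must be named by the network's nodes")
    members <- members[nodes]
    members <- lapply(members, sort_ids)
  }
  new_reaction_network(nodes, em, as.integer(level), members)
}

new_reaction_network <- function(nodes, edges, level = 0L, members = NULL) {
  structure(
    list(nodes = nodes, edges = edges, level = level, members = members),
    class = "reaction_network"
  )
}

#' @rdname reaction_network
#' @param net,x A `reaction_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname reaction_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname reaction_network
#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> level %d: %d nodes, %d edges\n",
              x$level, n_nodes(x), n_edges(x)))
  if (n_edges(x)) {
    show <- utils::head(sprintf("%s -> %s", x$edges[, 1], x$edges[, 2]), 8L)
    cat(" ", paste(show, collapse = ", "),
        if (n_edges(x) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# member sets as a named list, defaulting to the identity at level 0
node_members <- function(net) {
  if (!is.null(net$members)) return(net$members)
  stats::setNames(as.list(net$nodes), net$nodes)
}

#' Read and write tab-separated edge lists
#'
#' One directed edge per non-comment line, two whitespace-separated
#' identifiers. Lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return `read_edge_list()` returns a level-0 [reaction_network()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  check_that(file.exists(path), "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(reaction_network())
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- idx[which(nfield != 2L)[1]]
    stop_validation("malformed edge list: line %d of '%s' does not have two fields",
                    bad, path)
  }
  em <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  reaction_network(em)
}

#' @rdname read_edge_list
#' @param net A `reaction_network`.
#' @export
write_edge_list <- function(net, path) {
  check_that(inherits(net, "reaction_network"), "net must be a reaction_network")
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fetch a node's incident-edge "other endpoints" (one entry per edge, so a
# reciprocal pair contributes twice); returns a named list over all nodes
incidence_list <- function(net) {
  inc <- stats::setNames(vector("list", n_nodes(net)), net$nodes)
  if (n_edges(net)) {
    sp <- split(c(net$edges[, 2], net$edges[, 1]),
                factor(c(net$edges[, 1], net$edges[, 2]), levels = net$nodes))
    inc[names(sp)] <- sp
  }
  inc
}

# unique undirected neighbor sets
neighbor_list <- function(net) {
  lapply(incidence_list(net), function(v) sort_ids(v))
}
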