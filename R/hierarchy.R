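#' Compression hierarchies
#'
#' A `compression_hierarchy` records the per-level networks `P^0 ... P^c`
#' produced by MDS compression, the supernode table (children at the level
#' below, level-0 member reactions, and the internal edges swallowed by each
#' merge), and the ordered log of merge steps. The step log keeps, for every
#' merge, whether a non-compressed node of active degree one existed at the
#' time (`degree_one_available`); steps where it did not are the `s` count
#' used by the optimality bounds.
#'
#' @name compression_hierarchy
#' @param h A `compression_hierarchy`.
NULL

new_compression_hierarchy <- function(levels, supernodes, steps) {
  structure(list(levels = levels, supernodes = supernodes, steps = steps),
            class = "compression_hierarchy")
}

empty_supernode_table <- function() {
  tibble::new_tibble(list(level = integer(), id = character(),
                          children = list(), members = list(),
                          internal_edges = list()), nrow = 0L)
}

empty_step_table <- function() {
  tibble::new_tibble(list(level = integer(), step = integer(),
                          v_a = character(), v_b = character(),
                          supernode = character(),
                          degree_one_available = logical()), nrow = 0L)
}

#' @export
print.compression_hierarchy <- function(x, ...) {
  counts <- vapply(x$levels, function(n) c(n_nodes(n), n_edges(n)), integer(2))
  cat(sprintf("<compression_hierarchy> %d level(s)\n", length(x$levels)))
  cat(sprintf("  level %d: %d nodes, %d edges\n",
              seq_along(x$levels) - 1L, counts[1, ], counts[2, ]), sep = "")
  invisible(x)
}

#' @rdname compression_hierarchy
#' @details `max_level()` returns `c`, the deepest compression level held.
#' @export
max_level <- function(h) length(h$levels) - 1L

#' Level-0 member reactions of a node in a hierarchy
#'
#' @param h A `compression_hierarchy`.
#' @param level Level of the node (0 to `max_level(h)`).
#' @param node_id Node identifier at that level.
#' @return Character vector of level-0 reaction identifiers.
#' @export
members_of <- function(h, level, node_id) {
  check_that(inherits(h, "compression_hierarchy"), "h must be a compression_hierarchy")
  check_that(is_count(level) && level <= max_level(h),
             "level %s is not present in the hierarchy", format(level))
  net <- h$levels[[level + 1L]]
  if (!node_id %in% net$nodes) {
    stop_validation("node '%s' does not exist at level %d", node_id, level)
  }
  node_members(net)[[node_id]]
}

validate_hierarchy <- function(h) {
  check_that(inherits(h, "compression_hierarchy"), "not a compression_hierarchy")
  base <- h$levels[[1]]$nodes
  for (x in seq_along(h$levels)) {
    net <- h$levels[[x]]
    mem <- node_members(net)
    all_members <- unlist(mem, use.names = FALSE)
    check_that(!anyDuplicated(all_members) && setequal(all_members, base),
               "members of level %d do not partition the level-0 node set", x - 1L)
    bound <- 2^net$level
    check_that(all(lengths(mem) >= 1 & lengths(mem) <= bound),
               "a node at level %d violates the [1, 2^level] member bound", net$level)
    if (x > 1L) {
      n_steps <- sum(h$steps$level == net$level)
      check_that(n_nodes(net) == n_nodes(h$levels[[x - 1L]]) - n_steps,
                 "node count at level %d inconsistent with the step log", net$level)
    }
  }
  invisible(h)
}

hierarchy_schema_version <- 1L

#' Serialize a compression hierarchy to JSON
#'
#' The on-disk form is a versioned JSON document holding the per-level node
#' and edge sets, the supernode table, and the merge-step log. The round
#' trip `read_hierarchy(write_hierarchy(h, path))` is structurally lossless.
#'
#' @param h A `compression_hierarchy`.
#' @param path File path.
#' @return `write_hierarchy()` returns `path` invisibly; `read_hierarchy()`
#'   returns the reconstructed, validated `compression_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  validate_hierarchy(h)
  edges_df <- function(em) {
    if (nrow(em)) data.frame(from = em[, 1], to = em[, 2]) else list()
  }
  doc <- list(
    version = hierarchy_schema_version,
    levels = lapply(h$levels, function(net) {
      list(level = net$level, nodes = net$nodes, edges = edges_df(net$edges))
    }),
    supernodes = lapply(seq_len(nrow(h$supernodes)), function(i) {
      list(id = h$supernodes$id[i], level = h$supernodes$level[i],
           children = h$supernodes$children[[i]],
           members = h$supernodes$members[[i]],
           internal_edges = edges_df(h$supernodes$internal_edges[[i]]))
    }),
    steps = h$steps
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  check_that(file.exists(path), "file '%s' does not exist", path)
  # no jsonlite simplification: its data-dependent heuristics would make the
  # parsed shape depend on the hierarchy's content
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_that(identical(as.integer(doc$version), hierarchy_schema_version),
             "hierarchy schema version %s not supported", format(doc$version))
  as_edge_matrix <- function(rows) {
    if (length(rows)) {
      m <- cbind(vapply(rows, function(e) as.character(e$from), character(1)),
                 vapply(rows, function(e) as.character(e$to), character(1)))
    } else {
      m <- matrix(character(), ncol = 2L)
    }
    colnames(m) <- c("from", "to")
    m
  }
  sup_raw <- doc$supernodes
  if (length(sup_raw)) {
    sup <- tibble::tibble(
      level = vapply(sup_raw, function(s) as.integer(s$level), integer(1)),
      id = vapply(sup_raw, function(s) as.character(s$id), character(1)),
      children = lapply(sup_raw, function(s) as.character(unlist(s$children))),
      members = lapply(sup_raw, function(s) sort_ids(unlist(s$members))),
      internal_edges = lapply(sup_raw, function(s) as_edge_matrix(s$internal_edges))
    )
    sup <- sup[order_ids(sprintf("%06d", sup$level), sup$id), ]
  } else {
    sup <- empty_supernode_table()
  }
  levels <- lapply(doc$levels, function(lv) {
    lv_level <- as.integer(lv$level)
    members <- NULL
    if (lv_level > 0L) {
      rows <- sup[sup$level == lv_level, ]
      members <- stats::setNames(rows$members, rows$id)
    }
    reaction_network(as_edge_matrix(lv$edges),
                     nodes = as.character(unlist(lv$nodes)),
                     level = lv_level, members = members)
  })
  steps <- if (length(doc$steps)) {
    tibble::tibble(
      level = vapply(doc$steps, function(s) as.integer(s$level), integer(1)),
      step = vapply(doc$steps, function(s) as.integer(s$step), integer(1)),
      v_a = vapply(doc$steps, function(s) as.character(s$v_a), character(1)),
      v_b = vapply(doc$steps, function(s) as.character(s$v_b), character(1)),
      supernode = vapply(doc$steps, function(s) as.character(s$supernode),
                         character(1)),
      degree_one_available = vapply(doc$steps,
                                    function(s) as.logical(s$degree_one_available),
                                    logical(1))
    )
  } else {
    empty_step_table()
  }
  h <- new_compression_hierarchy(levels, sup, steps)
  validate_hierarchy(h)
  h
}
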