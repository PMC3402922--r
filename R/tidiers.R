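# broom-style tidiers bridging the S3 containers into tibbles

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reaction network into its edge table
#'
#' @param x A [reaction_network()].
#' @param ... Unused.
#' @return A tibble with columns `from` and `to`.
#' @method tidy reaction_network
#' @export
tidy.reaction_network <- function(x, ...) {
  tibble::tibble(from = x$edges[, 1], to = x$edges[, 2])
}

#' @rdname tidy.reaction_network
#' @method glance reaction_network
#' @export
glance.reaction_network <- function(x, ...) {
  tibble::tibble(level = x$level, nodes = n_nodes(x), edges = n_edges(x))
}

#' Tidy a compression hierarchy into per-level counts
#'
#' @param x A [compression_hierarchy].
#' @param ... Unused.
#' @return One row per level: `level`, `nodes`, `edges`, `steps`.
#' @method tidy compression_hierarchy
#' @export
tidy.compression_hierarchy <- function(x, ...) {
  tibble::tibble(
    level = vapply(x$levels, function(net) net$level, integer(1)),
    nodes = vapply(x$levels, n_nodes, integer(1)),
    edges = vapply(x$levels, n_edges, integer(1)),
    steps = vapply(vapply(x$levels, function(net) net$level, integer(1)),
                   function(lv) sum(x$steps$level == lv), integer(1))
  )
}

#' @rdname tidy.compression_hierarchy
#' @method glance compression_hierarchy
#' @export
glance.compression_hierarchy <- function(x, ...) {
  tibble::tibble(
    c = max_level(x),
    n = n_nodes(x$levels[[1]]),
    n_compressed = n_nodes(x$levels[[length(x$levels)]]),
    mds_steps = nrow(x$steps),
    s = sum(!x$steps$degree_one_available)
  )
}

#' Tidy an alignment into its mapping table
#'
#' @param x A `network_alignment` from [align_networks()].
#' @param ... Unused.
#' @return The selected mappings as a tibble.
#' @method tidy network_alignment
#' @export
tidy.network_alignment <- function(x, ...) {
  x$mappings
}

#' @rdname tidy.network_alignment
#' @method glance network_alignment
#' @export
glance.network_alignment <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    support_dim = x$support_dim,
    support_entries = x$support_dim^2,
    n_mappings = nrow(x$mappings),
    total_score = sum(x$mappings$score)
  )
}

#' Tidy a three-phase alignment into its reaction-level mappings
#'
#' @param x A `compressed_alignment` from [compress_align_refine()].
#' @param ... Unused.
#' @return The final level-0 mapping tibble.
#' @method tidy compressed_alignment
#' @export
tidy.compressed_alignment <- function(x, ...) {
  x$final
}

#' @rdname tidy.compressed_alignment
#' @method glance compressed_alignment
#' @export
glance.compressed_alignment <- function(x, ...) {
  tibble::tibble(
    c = x$c,
    k = x$k,
    n_mappings = nrow(x$final),
    compressed_support_dim = x$compressed$support_dim,
    total_score = sum(x$final$score)
  )
}
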