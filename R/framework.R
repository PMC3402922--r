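# Three-phase orchestration: compress -> align in the compressed domain ->
# recursively refine supernode mappings back to the reaction level; plus the
# planner that chooses the compression level and decides whether compressing
# pays off at all.

#' Optimal compression level for a query pair
#'
#' The compression level minimizing the expected cost of the framework for
#' networks of sizes `n` and `m` and subnetwork bound `k`:
#' `c = log2(n * m^2 / k^2) / 8`, with `n` the smaller size. The suggested
#' integer level is the nearest integer, floored at zero.
#'
#' @param n,m Network sizes (positive).
#' @param k Subnetwork size bound (positive).
#' @return A one-row tibble with `c_real` and `c_level`.
#' @examples
#' optimal_c(100, 100, 2)  # c_real 2.24, c_level 2
#' @export
optimal_c <- function(n, m, k) {
  check_that(is_count(n, 1) && is_count(m, 1) && is_count(k, 1),
             "n, m and k must be positive integers")
  if (n > m) { tmp <- n; n <- m; m <- tmp }
  c_real <- log2(n * m^2 / k^2) / 8
  tibble::tibble(c_real = c_real, c_level = max(0L, as.integer(round(c_real))))
}

#' Subnetwork counts feeding the compress decision
#'
#' Enumerates the subnetworks of both query networks in the original and
#' the `c`-level compressed domain and returns the counts (`n_k`, `m_k`,
#' `n_k_c`, `m_k_c`) together with the observed subnetwork density ratios
#' `alpha_k = N_k / n` and `beta_k = M_k / m`.
#'
#' @param net1,net2 Level-0 [reaction_network()] objects.
#' @param k Subnetwork size bound.
#' @param c Compression level to evaluate.
#' @return A one-row tibble.
#' @export
planner_inputs <- function(net1, net2, k, c) {
  check_that(is_count(c, 1), "c must be a positive integer")
  n <- n_nodes(net1)
  m <- n_nodes(net2)
  n_k <- nrow(enumerate_subnetworks(net1, k))
  m_k <- nrow(enumerate_subnetworks(net2, k))
  h1 <- mds_compress(net1, c)
  h2 <- mds_compress(net2, c)
  n_k_c <- nrow(enumerate_subnetworks(h1$levels[[c + 1L]], k))
  m_k_c <- nrow(enumerate_subnetworks(h2$levels[[c + 1L]], k))
  tibble::tibble(n = n, m = m, k = as.integer(k), c = as.integer(c),
                 n_k = n_k, m_k = m_k, n_k_c = n_k_c, m_k_c = m_k_c,
                 alpha_k = n_k / n, beta_k = m_k / m)
}

#' Should the alignment be run in the compressed domain?
#'
#' Computes `y = (N_k^c * M_k^c) / (N_k * M_k)`, the ratio of the
#' candidate-space sizes with and without compression. Compression is
#' predicted to pay off when `y <= 0.5`.
#'
#' @param inputs A one-row data frame with columns `n_k`, `m_k`, `n_k_c`,
#'   `m_k_c` (e.g. from [planner_inputs()]).
#' @return A one-row tibble with `ratio` and `compress`.
#' @export
should_compress <- function(inputs) {
  inputs <- as.data.frame(inputs)
  need <- c("n_k", "m_k", "n_k_c", "m_k_c")
  check_that(all(need %in% names(inputs)),
             "inputs must have columns n_k, m_k, n_k_c, m_k_c")
  counts <- as.numeric(inputs[1, need])
  check_that(all(is.finite(counts)) && all(counts > 0),
             "subnetwork counts must be positive")
  ratio <- (inputs$n_k_c[1] * inputs$m_k_c[1]) / (inputs$n_k[1] * inputs$m_k[1])
  tibble::tibble(ratio = ratio, compress = ratio <= 0.5)
}

# empty level-0 mapping table used by refinement
empty_refined <- function() {
  tibble::tibble(mapping_id = character(), left_id = character(),
                 right_id = character(), left_members = list(),
                 right_members = list(), score = numeric())
}

refined_row <- function(left, right, score) {
  left <- sort_ids(left)
  right <- sort_ids(right)
  lid <- paste(left, collapse = ",")
  rid <- paste(right, collapse = ",")
  tibble::tibble(mapping_id = mapping_id(lid, rid), left_id = lid,
                 right_id = rid, left_members = list(left),
                 right_members = list(right), score = score)
}

#' Refine a compressed-domain mapping down to the reaction level
#'
#' Decompresses each side of a level-`level` mapping by one level
#' ([decompress_block()]), re-aligns the two small networks with the base
#' aligner, and recurses on every resulting mapping until level 0. At
#' recursion from level `x` the two instances hold at most `k * 2^x` and
#' `2^x` reactions; members of every refined mapping stay inside the input
#' mapping's supernodes. Supernode members left unmatched by an inner
#' alignment are dropped.
#'
#' @param left_nodes,right_nodes Node identifier vectors of the mapping's
#'   two sides at `level` (one side must be a single node).
#' @param h1,h2 [compression_hierarchy] objects of the two networks.
#' @param level Compression level of the mapping (`>= 0`).
#' @param k Subnetwork bound used for the inner alignments.
#' @param sim Reaction-level similarity.
#' @param score Score to attach when `level = 0` (pass-through base case).
#' @param ... Further arguments for [align_networks()].
#' @return A tibble of level-0 mappings (see [compress_align_refine()]).
#' @export
refine_mapping <- function(left_nodes, right_nodes, h1, h2, level, k = 1L,
                           sim = "uniform", score = NA_real_, ...) {
  check_that(is_count(level), "level must be a non-negative integer")
  if (level == 0L) {
    return(refined_row(left_nodes, right_nodes, score))
  }
  check_that(level <= max_level(h1) && level <= max_level(h2),
             "mapping level exceeds the hierarchies' depth")
  net_l <- decompress_block(h1, level, left_nodes)
  net_r <- decompress_block(h2, level, right_nodes)
  # recursion size bound: k*2^x reactions on the many side, 2^x on the other
  n_react_l <- length(unlist(node_members(net_l), use.names = FALSE))
  n_react_r <- length(unlist(node_members(net_r), use.names = FALSE))
  lo <- min(n_react_l, n_react_r)
  hi <- max(n_react_l, n_react_r)
  check_that(lo <= 2^level && hi <= k * 2^level,
             "refinement block exceeds the k*2^x / 2^x size bound")
  al <- align_networks(net_l, net_r, k = k, sim = sim, ...)
  if (!nrow(al$mappings)) return(empty_refined())
  parts <- lapply(seq_len(nrow(al$mappings)), function(i) {
    refine_mapping(al$mappings$left_nodes[[i]], al$mappings$right_nodes[[i]],
                   h1, h2, level - 1L, k = k, sim = sim,
                   score = al$mappings$score[i], ...)
  })
  dplyr::bind_rows(parts)
}

#' Compress, align, refine
#'
#' The full three-phase framework: both networks are compressed `c` levels
#' with [mds_compress()], aligned in the compressed domain with
#' [align_networks()], and every supernode mapping is refined recursively
#' back to the reaction level. With `c = 0` the pipeline degenerates to a
#' single base-aligner run.
#'
#' @param net1,net2 Level-0 [reaction_network()] objects.
#' @param c Compression levels (`>= 0`).
#' @param k Subnetwork size bound.
#' @param sim Reaction-level similarity.
#' @param ... Further arguments for [align_networks()].
#' @return A `compressed_alignment`: `final` (tibble of conflict-free
#'   level-0 mappings), `compressed` (the compressed-domain
#'   `network_alignment`), `hierarchies`, and the parameters used.
#' @examples
#' toy <- toy_instance()
#' res <- compress_align_refine(toy$net1, toy$net2, c = 1, k = 1, sim = toy$sim)
#' res$final
#' @export
compress_align_refine <- function(net1, net2, c, k = 1L, sim = "uniform", ...) {
  check_that(is_count(c), "c must be a non-negative integer")
  if (c == 0L) {
    base <- align_networks(net1, net2, k = k, sim = sim, ...)
    final <- if (nrow(base$mappings)) {
      dplyr::bind_rows(lapply(seq_len(nrow(base$mappings)), function(i) {
        refined_row(base$mappings$left_nodes[[i]],
                    base$mappings$right_nodes[[i]], base$mappings$score[i])
      }))
    } else {
      empty_refined()
    }
    return(new_compressed_alignment(final, base, NULL, 0L, k))
  }
  h1 <- mds_compress(net1, c)
  h2 <- mds_compress(net2, c)
  comp <- align_networks(h1$levels[[c + 1L]], h2$levels[[c + 1L]],
                         k = k, sim = sim, ...)
  final <- if (nrow(comp$mappings)) {
    dplyr::bind_rows(lapply(seq_len(nrow(comp$mappings)), function(i) {
      refine_mapping(comp$mappings$left_nodes[[i]],
                     comp$mappings$right_nodes[[i]],
                     h1, h2, c, k = k, sim = sim,
                     score = comp$mappings$score[i], ...)
    }))
  } else {
    empty_refined()
  }
  # block disjointness of supernode mappings guarantees reaction-level
  # conflict-freedom; assert it anyway
  check_that(!anyDuplicated(unlist(final$left_members)) &&
               !anyDuplicated(unlist(final$right_members)),
             "refined alignment is not conflict-free")
  new_compressed_alignment(final, comp, list(h1, h2), as.integer(c), k)
}

new_compressed_alignment <- function(final, compressed, hierarchies, c, k) {
  structure(
    list(final = final, compressed = compressed, hierarchies = hierarchies,
         c = c, k = as.integer(k)),
    class = "compressed_alignment"
  )
}

#' @export
print.compressed_alignment <- function(x, ...) {
  cat(sprintf("<compressed_alignment> c = %d, k = %d: %d reaction-level mapping(s)\n",
              x$c, x$k, nrow(x$final)))
  if (nrow(x$final)) print(utils::head(x$final[, c("mapping_id", "score")], 10L))
  invisible(x)
}
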