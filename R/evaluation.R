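# Accuracy evaluation (compressed vs. original domain), score
# back-projection, correlation, degree analytics, compression-rate reports.

# lookup of original-domain reaction-pair scores; pairs never scored
# contribute 0 (the conservative reading: averages may then underestimate)
pair_score_lookup <- function(scores) {
  if (is.matrix(scores)) {
    m <- scores
  } else {
    scores <- as.data.frame(scores)
    check_that(ncol(scores) >= 3L, "scores need columns id1, id2, score")
    ids1 <- sort_ids(scores[[1]])
    ids2 <- sort_ids(scores[[2]])
    m <- matrix(NA_real_, length(ids1), length(ids2),
                dimnames = list(ids1, ids2))
    m[cbind(as.character(scores[[1]]), as.character(scores[[2]]))] <-
      as.numeric(scores[[3]])
  }
  function(left, right) {
    out <- matrix(0, length(left), length(right))
    ri <- match(left, rownames(m))
    ci <- match(right, colnames(m))
    ok <- which(!is.na(ri))
    for (i in ok) {
      vals <- m[ri[i], ci[!is.na(ci)]]
      out[i, !is.na(ci)] <- ifelse(is.na(vals), 0, vals)
    }
    out
  }
}

#' Back-projected score of a compressed-domain mapping
#'
#' The mean of original-domain reaction-pair scores over the full cross
#' product of the mapping's member sets; a supernode pair containing
#' members `{r1, r2}` and `{r1', r2', r3'}` averages the six constituent
#' pair scores. Pairs absent from `scores` contribute zero.
#'
#' @param left,right Nonempty character vectors of level-0 reaction
#'   identifiers (the two member sets).
#' @param scores Reaction-pair scores: a matrix with identifier dimnames or
#'   a long data frame (`id1`, `id2`, `score`).
#' @return A single real score.
#' @export
backproject_score <- function(left, right, scores) {
  check_that(length(left) >= 1 && length(right) >= 1,
             "member sets must be nonempty")
  lookup <- if (is.function(scores)) scores else pair_score_lookup(scores)
  mean(lookup(left, right))
}

#' Pearson correlation with explicit preconditions
#'
#' Standard sample Pearson correlation, rejecting unequal lengths,
#' fewer than two observations, non-finite values, and zero variance
#' (where the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @return A real number in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  check_that(length(x) == length(y), "x and y must have equal length")
  check_that(length(x) >= 2, "need at least two observations")
  check_that(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  check_that(stats::sd(x) > 0 && stats::sd(y) > 0,
             "correlation undefined for zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Accuracy of compressed-domain alignment scores
#'
#' Runs the framework in the compressed domain and the base aligner in the
#' original domain, back-projects every compressed-domain candidate
#' mapping's score onto the original reaction-pair scores, and returns the
#' Pearson correlation between the two score sets over the whole
#' compressed-domain candidate list. At `c = 0` the two score sets coincide
#' and the accuracy is exactly 1.
#'
#' @inheritParams compress_align_refine
#' @param detail If `TRUE`, also return the per-candidate score pairs.
#' @return The correlation (a real), or with `detail = TRUE` a list with
#'   `accuracy` and a `scores` tibble (`mapping_id`, `compressed_score`,
#'   `backprojected_score`).
#' @export
alignment_accuracy <- function(net1, net2, c, k = 1L, sim = "uniform",
                               detail = FALSE, ...) {
  check_that(is_count(c), "c must be a non-negative integer")
  base <- align_networks(net1, net2, k = k, sim = sim, ...)
  singles <- base$candidates[base$candidates$left_size == 1L &
                               base$candidates$right_size == 1L, ]
  pair_scores <- tibble::tibble(
    id1 = vapply(singles$left_nodes, `[[`, character(1), 1L),
    id2 = vapply(singles$right_nodes, `[[`, character(1), 1L),
    score = singles$score
  )
  if (c == 0L) {
    out <- tibble::tibble(mapping_id = base$candidates$mapping_id,
                          compressed_score = base$candidates$score,
                          backprojected_score = base$candidates$score)
    acc <- 1
  } else {
    res <- compress_align_refine(net1, net2, c = c, k = k, sim = sim, ...)
    cands <- res$compressed$candidates
    lookup <- pair_score_lookup(similarity_like_matrix(pair_scores))
    back <- vapply(seq_len(nrow(cands)), function(i) {
      backproject_score(cands$left_members[[i]], cands$right_members[[i]],
                        lookup)
    }, numeric(1))
    out <- tibble::tibble(mapping_id = cands$mapping_id,
                          compressed_score = cands$score,
                          backprojected_score = back)
    acc <- pearson(out$compressed_score, out$backprojected_score)
  }
  if (detail) list(accuracy = acc, scores = out) else acc
}

similarity_like_matrix <- function(long) {
  ids1 <- sort_ids(long[[1]])
  ids2 <- sort_ids(long[[2]])
  m <- matrix(NA_real_, length(ids1), length(ids2),
              dimnames = list(ids1, ids2))
  m[cbind(as.character(long[[1]]), as.character(long[[2]]))] <-
    as.numeric(long[[3]])
  m
}

node_degrees <- function(net, direction = c("out", "in", "total")) {
  direction <- match.arg(direction)
  outd <- table(factor(net$edges[, 1], levels = net$nodes))
  ind <- table(factor(net$edges[, 2], levels = net$nodes))
  d <- switch(direction, out = outd, `in` = ind, total = outd + ind)
  stats::setNames(as.integer(d), net$nodes)
}

#' Degree histogram of a network
#'
#' Exact frequency of each in-, out-, or total degree. `range` restricts
#' the reported degrees (e.g. `c(2, 40)` to focus on the hub tail).
#'
#' @param net A [reaction_network()].
#' @param direction `"out"`, `"in"`, or `"total"`.
#' @param range Optional `c(min, max)` filter on the degree values.
#' @return A tibble with columns `degree` and `n`.
#' @export
degree_histogram <- function(net, direction = c("out", "in", "total"),
                             range = NULL) {
  d <- node_degrees(net, match.arg(direction))
  if (!length(d)) return(tibble::tibble(degree = integer(), n = integer()))
  tab <- table(d)
  out <- tibble::tibble(degree = as.integer(names(tab)),
                        n = as.integer(tab))
  if (!is.null(range)) {
    out <- out[out$degree >= range[1] & out$degree <= range[2], ]
  }
  out
}

#' Fraction of hub nodes
#'
#' Share of nodes whose degree exceeds `threshold` (out-degree by
#' default). In scale-free networks this hub fraction is small; multilevel
#' compression shifts degree mass upward, so the fraction grows with the
#' compression level.
#'
#' @inheritParams degree_histogram
#' @param threshold Degree cutoff (a node is a hub when strictly above it).
#' @return A real fraction in `[0, 1]`.
#' @export
hub_fraction <- function(net, threshold = 15, direction = c("out", "in", "total")) {
  d <- node_degrees(net, match.arg(direction))
  if (!length(d)) return(0)
  mean(d > threshold)
}

#' Per-level compression-rate report
#'
#' Mean node and edge counts per compression level over a collection of
#' hierarchies, optionally binned by the level-0 network size.
#'
#' @param hierarchies A [compression_hierarchy] or a list of them.
#' @param size_breaks Optional numeric breaks for binning by level-0 node
#'   count (passed to [cut()]).
#' @return A tibble with one row per (bin,) level.
#' @export
compression_report <- function(hierarchies, size_breaks = NULL) {
  if (inherits(hierarchies, "compression_hierarchy")) {
    hierarchies <- list(hierarchies)
  }
  rows <- dplyr::bind_rows(lapply(seq_along(hierarchies), function(i) {
    h <- hierarchies[[i]]
    tibble::tibble(
      hierarchy = i,
      size0 = n_nodes(h$levels[[1]]),
      level = vapply(h$levels, function(net) net$level, integer(1)),
      nodes = vapply(h$levels, n_nodes, integer(1)),
      edges = vapply(h$levels, n_edges, integer(1))
    )
  }))
  if (!is.null(size_breaks)) {
    rows$size_bin <- cut(rows$size0, breaks = size_breaks)
    grp <- dplyr::group_by(rows, .data$size_bin, .data$level)
  } else {
    grp <- dplyr::group_by(rows, .data$level)
  }
  dplyr::summarise(grp,
                   n_networks = dplyr::n(),
                   mean_nodes = mean(.data$nodes),
                   mean_edges = mean(.data$edges),
                   .groups = "drop")
}
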