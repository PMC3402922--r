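#' Reaction similarity lookups
#'
#' Pairwise reaction similarities feed the homology component of mapping
#' scores. A similarity can be given as the string `"uniform"` (every pair
#' scores 1), a numeric matrix with row names from one network and column
#' names from the other, or a long data frame with columns
#' `id1`, `id2`, `value`. Lookups treat identifier order symmetrically:
#' a pair absent in one orientation is looked up in the other.
#'
#' @param x A matrix or a data frame (`id1`, `id2`, `value`).
#' @return A named numeric matrix usable wherever a `sim` argument is
#'   accepted.
#' @export
similarity_table <- function(x) {
  if (is.matrix(x)) {
    check_that(!is.null(rownames(x)) && !is.null(colnames(x)),
               "similarity matrix needs row and column names")
    m <- x
  } else {
    x <- as.data.frame(x)
    check_that(ncol(x) >= 3L, "similarity table needs columns id1, id2, value")
    ids1 <- sort_ids(x[[1]])
    ids2 <- sort_ids(x[[2]])
    m <- matrix(NA_real_, length(ids1), length(ids2),
                dimnames = list(ids1, ids2))
    m[cbind(as.character(x[[1]]), as.character(x[[2]]))] <- as.numeric(x[[3]])
  }
  bad <- m[!is.na(m)]
  check_that(all(bad >= 0 & bad <= 1), "similarity values must lie in [0, 1]")
  m
}

is_uniform_sim <- function(sim) {
  is.character(sim) && length(sim) == 1L && identical(sim, "uniform")
}

as_similarity <- function(sim) {
  if (is_uniform_sim(sim)) return("uniform")
  similarity_table(sim)
}

# value matrix for ids1 x ids2; errors (naming the identifier) on misses
sim_values <- function(sim, ids1, ids2) {
  if (is_uniform_sim(sim)) {
    return(matrix(1, length(ids1), length(ids2), dimnames = list(ids1, ids2)))
  }
  out <- matrix(NA_real_, length(ids1), length(ids2),
                dimnames = list(ids1, ids2))
  in_r1 <- ids1 %in% rownames(sim)
  in_c2 <- ids2 %in% colnames(sim)
  if (any(in_r1) && any(in_c2)) {
    out[in_r1, in_c2] <- sim[ids1[in_r1], ids2[in_c2], drop = FALSE]
  }
  # symmetric orientation for anything still missing
  if (anyNA(out)) {
    in_c1 <- ids1 %in% colnames(sim)
    in_r2 <- ids2 %in% rownames(sim)
    if (any(in_c1) && any(in_r2)) {
      flip <- t(sim[ids2[in_r2], ids1[in_c1], drop = FALSE])
      sub <- out[in_c1, in_r2, drop = FALSE]
      sub[is.na(sub)] <- flip[is.na(sub)]
      out[in_c1, in_r2] <- sub
    }
  }
  if (anyNA(out)) {
    miss <- which(is.na(out), arr.ind = TRUE)[1, ]
    known <- ids1[miss[1]] %in% c(rownames(sim), colnames(sim))
    stop_validation("similarity is missing identifier '%s'",
                    if (known) ids2[miss[2]] else ids1[miss[1]])
  }
  out
}

#' Seeded random similarity matrix
#'
#' Uniform values in `[0, 1]` for every pair of identifiers; a pure
#' function of its seed.
#'
#' @param ids1,ids2 Identifier vectors of the two networks.
#' @param seed Integer seed.
#' @return A similarity matrix (see [similarity_table()]).
#' @export
random_similarity <- function(ids1, ids2, seed) {
  check_that(is_count(seed), "seed must be a non-negative integer")
  ids1 <- sort_ids(ids1)
  ids2 <- sort_ids(ids2)
  withr::with_seed(as.integer(seed), {
    matrix(stats::runif(length(ids1) * length(ids2)),
           length(ids1), length(ids2), dimnames = list(ids1, ids2))
  })
}
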