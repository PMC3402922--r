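# fixtures and independent brute-force oracles used across the suite

make_path <- function(n, ids = letters[seq_len(n)]) {
  reaction_network(data.frame(from = ids[-n], to = ids[-1]))
}

make_star <- function(leaves = 3) {
  reaction_network(data.frame(from = "c0", to = paste0("l", seq_len(leaves))))
}

identity_sim <- function(ids) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  m
}

# seeded random simple directed network (possibly disconnected)
random_net <- function(n, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p
    reaction_network(pairs[keep, ], nodes = ids)
  })
}

# brute-force enumeration of connected node sets of size <= k
oracle_connected_sets <- function(net, k) {
  nodes <- net$nodes
  und <- unique(rbind(net$edges, net$edges[, 2:1, drop = FALSE]))
  connected <- function(set) {
    if (length(set) == 1L) return(TRUE)
    reached <- set[1]
    repeat {
      grow <- unique(c(reached, und[und[, 1] %in% reached & und[, 2] %in% set, 2]))
      if (length(grow) == length(reached)) break
      reached <- grow
    }
    length(reached) == length(set)
  }
  out <- character(0)
  for (size in seq_len(min(k, length(nodes)))) {
    sets <- utils::combn(nodes, size, simplify = FALSE)
    ok <- vapply(sets, connected, logical(1))
    out <- c(out, vapply(sets[ok], function(s) paste(sort(s), collapse = ","),
                         character(1)))
  }
  sort(out)
}

# independent recurrence oracle for the score iteration
oracle_iterate <- function(S, h, gamma, n_iter = 100) {
  h <- h / sum(h)
  s <- h
  for (i in seq_len(n_iter)) s <- as.vector(gamma * (S %*% s) + (1 - gamma) * h)
  s / sum(s)
}
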