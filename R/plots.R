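# ggplot2 views of the result types

#' Plot a degree distribution
#'
#' Bar chart of the degree frequencies of one network, or of every level
#' of a hierarchy (facetted), to visualize the shift away from a power-law
#' shape under repeated compression.
#'
#' @param x A [reaction_network()] or [compression_hierarchy].
#' @param direction `"out"`, `"in"`, or `"total"`.
#' @param range Optional degree range filter, e.g. `c(2, 40)`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(x, direction = "out", range = NULL) {
  if (inherits(x, "compression_hierarchy")) {
    df <- dplyr::bind_rows(lapply(x$levels, function(net) {
      dh <- degree_histogram(net, direction, range)
      dh$level <- net$level
      dh
    }))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~level, labeller = ggplot2::label_both)
  } else {
    df <- degree_histogram(x, direction, range)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
      ggplot2::geom_col()
  }
  p + ggplot2::labs(x = sprintf("%s-degree", direction), y = "frequency")
}

#' @method autoplot compression_hierarchy
#' @export
autoplot.compression_hierarchy <- function(object, ...) {
  df <- tidy(object)
  long <- tibble::tibble(
    level = rep(df$level, 2L),
    count = c(df$nodes, df$edges),
    what = rep(c("nodes", "edges"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$count,
                                     colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "compression level", y = "count", colour = NULL)
}

#' @method autoplot network_alignment
#' @export
autoplot.network_alignment <- function(object, ...) {
  df <- object$mappings
  df$mapping_id <- factor(df$mapping_id, levels = df$mapping_id[order(df$score)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$mapping_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mapping score", y = NULL)
}
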