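#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Degree distribution plot
#'
#' Histogram of node degrees; the real co-occurrence networks this package
#' targets show a unimodal, near-normal degree distribution.
#'
#' @param net An `adn` object.
#' @param binwidth Histogram bin width (default 1).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net, binwidth = 1) {
  stopifnot(inherits(net, "adn"))
  deg <- igraph::degree(adn_igraph(net))
  df <- tibble::tibble(degree = as.numeric(deg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Degree", y = "Node count",
                  title = "Degree distribution")
}

#' @describeIn plot_degree_distribution autoplot method for networks.
#' @param object An `adn` object.
#' @param ... Passed to [plot_degree_distribution()].
#' @method autoplot adn
#' @export
autoplot.adn <- function(object, ...) plot_degree_distribution(object, ...)

#' Motif synergy distribution on log-log axes
#'
#' Plots the [synergy_distribution()] of positive per-motif synergies with
#' logarithmic axes, the standard view of a heavy-tailed distribution.
#'
#' @param synergy An `mpr_synergy` object.
#' @param bins Passed to [synergy_distribution()].
#' @return A ggplot object.
#' @export
plot_synergy_distribution <- function(synergy, bins = NULL) {
  dist <- synergy_distribution(synergy, bins = bins)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin_center,
                                     y = .data$probability)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Motif synergy strength (bits)",
                  y = "Empirical probability",
                  title = "Motif synergy distribution")
}

#' @describeIn plot_synergy_distribution autoplot method.
#' @param object An `mpr_synergy` object.
#' @param ... Passed to [plot_synergy_distribution()].
#' @method autoplot mpr_synergy
#' @export
autoplot.mpr_synergy <- function(object, ...) {
  plot_synergy_distribution(object, ...)
}

#' CCDF curves of one or several score vectors
#'
#' @param scores A tibble with `node`, `score`, or a named list of such
#'   tibbles (one CCDF curve per list element).
#' @return A ggplot object.
#' @export
plot_ccdf <- function(scores) {
  if (is.data.frame(scores)) scores <- list(scores = scores)
  curves <- dplyr::bind_rows(lapply(scores, ccdf), .id = "algorithm")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$score, y = .data$ccdf,
                                       colour = .data$algorithm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Score", y = "P(X ≥ x)", title = "Ranking CCDF")
}

#' @describeIn plot_ccdf autoplot method for PageRank scores.
#' @param object A `pagerank_scores` object.
#' @param ... Unused.
#' @method autoplot pagerank_scores
#' @export
autoplot.pagerank_scores <- function(object, ...) {
  plot_ccdf(stats::setNames(list(tibble::as_tibble(object)),
                            attr(object, "method")))
}

#' @describeIn evaluate_all autoplot method: metric bars per algorithm.
#' @param object An `adn_evaluation` object.
#' @method autoplot adn_evaluation
#' @export
autoplot.adn_evaluation <- function(object, ...) {
  long <- tidy.adn_evaluation(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Scorer evaluation")
}
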