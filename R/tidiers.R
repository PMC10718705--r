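#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn mpr_scores tidy method: node, score and global rank (ties
#'   broken lexicographically by code).
#' @param x A `pagerank_scores` object.
#' @param ... Unused.
#' @method tidy pagerank_scores
#' @export
tidy.pagerank_scores <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$node)
  out$rank <- seq_len(nrow(out))
  out
}

#' @describeIn mpr_scores glance method: one-row convergence summary.
#' @method glance pagerank_scores
#' @export
glance.pagerank_scores <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n_nodes = nrow(x),
    damping = attr(x, "damping"),
    iterations = attr(x, "iterations"),
    residual = attr(x, "residual"),
    converged = attr(x, "converged")
  )
}

#' @describeIn synergy_matrix tidy method: the per-motif table with
#'   unclamped synergy values.
#' @param x An `mpr_synergy` object.
#' @param ... Unused.
#' @method tidy mpr_synergy
#' @export
tidy.mpr_synergy <- function(x, ...) tibble::as_tibble(x$motifs)

#' @describeIn synergy_matrix glance method: motif count, network EI,
#'   number of negative (clamped) synergies and total clamped synergy mass.
#' @method glance mpr_synergy
#' @export
glance.mpr_synergy <- function(x, ...) {
  tibble::tibble(
    n_motifs = nrow(x$motifs),
    ei_g = x$ei_g,
    n_negative = sum(x$motifs$ei_delta < 0),
    total_synergy = sum(pmax(x$motifs$ei_delta, 0))
  )
}

#' @describeIn evaluate_all tidy method: long form, one row per
#'   algorithm-metric pair.
#' @param x An `adn_evaluation` object.
#' @param ... Unused.
#' @method tidy adn_evaluation
#' @export
tidy.adn_evaluation <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("algorithm", "resolution", "efficiency",
                             "accuracy")],
    -"algorithm", names_to = "metric", values_to = "value"
  )
}

#' @describeIn evaluate_all glance method: evaluation settings.
#' @method glance adn_evaluation
#' @export
glance.adn_evaluation <- function(x, ...) {
  tibble::tibble(
    n_algorithms = nrow(x),
    k = attr(x, "k"),
    runs = attr(x, "runs"),
    seed = attr(x, "seed")
  )
}

#' @describeIn build_adn tidy method: the edge list as a plain tibble.
#' @param x An `adn` object.
#' @param ... Unused.
#' @method tidy adn
#' @export
tidy.adn <- function(x, ...) tibble::as_tibble(unclass_adn(x))

#' @describeIn build_adn glance method: the [network_attributes()] row
#'   without the histogram column.
#' @method glance adn
#' @export
glance.adn <- function(x, ...) {
  network_attributes(x)[, c("n_nodes", "n_edges", "avg_weighted_degree",
                            "avg_clustering")]
}

unclass_adn <- function(x) {
  class(x) <- setdiff(class(x), "adn")
  attr(x, "nodes") <- NULL
  x
}
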