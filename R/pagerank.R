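#' Row-stochastic transition matrix from a nonnegative weight matrix
#'
#' \eqn{P_{ij} = H_{ij} / \sum_j H_{ij}}. Dangling rows (all-zero) are
#' replaced by the uniform row \eqn{1/N} so that the matrix stays stochastic
#' and the PageRank iteration's convergence guarantee applies.
#'
#' @param H Nonnegative square matrix (raw co-occurrence weights `W` or the
#'   synergy matrix `S`).
#' @return A row-stochastic matrix of the same dimension and dimnames.
#' @export
transition_matrix <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("`H` must be square", call. = FALSE)
  if (any(H < 0)) stop("`H` must be nonnegative", call. = FALSE)
  n <- nrow(H)
  s <- rowSums(H)
  P <- H / ifelse(s > 0, s, 1)
  if (any(s == 0)) P[s == 0, ] <- 1 / n
  P
}

new_pagerank_scores <- function(node, score, damping, iterations, residual,
                                converged, method = "pagerank") {
  structure(
    tibble::tibble(node = node, score = score),
    damping = damping, iterations = iterations, residual = residual,
    converged = converged, method = method,
    class = c("pagerank_scores", class(tibble::tibble()))
  )
}

#' PageRank by power iteration
#'
#' Iterates \eqn{x_t = d P^T x_{t-1} + (1-d)/N \, e} from the uniform vector
#' until the L1 change between iterates is at most `tol`. Since `P` is
#' row-stochastic the iteration conserves total mass 1 and always converges.
#'
#' @param P Row-stochastic matrix, e.g. from [transition_matrix()].
#' @param damping Damping factor d in (0,1); the complementary mass
#'   teleports uniformly. Default 0.85.
#' @param tol L1 convergence tolerance. Default 1e-10.
#' @param max_iter Iteration cap; if reached, the result carries a warning
#'   and `converged = FALSE`.
#' @return A `pagerank_scores` tibble (`node`, `score`), scores summing to 1,
#'   with damping/iterations/residual/converged recorded as attributes.
#' @export
pagerank <- function(P, damping = 0.85, tol = 1e-10, max_iter = 1000) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < 0)) {
    stop("`P` must be row-stochastic; see transition_matrix()", call. = FALSE)
  }
  if (damping <= 0 || damping >= 1) stop("`damping` must be in (0,1)", call. = FALSE)
  n <- nrow(P)
  nodes <- rownames(P)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(n))
  x <- rep(1 / n, n)
  tP <- t(P)
  teleport <- (1 - damping) / n
  res <- Inf
  iters <- 0L
  while (iters < max_iter) {
    x_new <- damping * as.numeric(tP %*% x) + teleport
    res <- sum(abs(x_new - x))
    x <- x_new
    iters <- iters + 1L
    if (res <= tol) break
  }
  converged <- res <= tol
  if (!converged) {
    warning("pagerank did not converge in ", max_iter,
            " iterations (residual ", signif(res, 3), ")", call. = FALSE)
  }
  new_pagerank_scores(nodes, x / sum(x), damping, iters, res, converged)
}

#' Motif-based PageRank (MPR) node scores
#'
#' The full scorer: the pairwise synergy-strength matrix `S` (aggregated
#' triangle effective-information drops, [synergy_matrix()]) replaces the raw
#' adjacency weights in the PageRank transition matrix, so high scores mark
#' nodes embedded in strongly synergistic triangles rather than merely
#' heavily weighted edges. Nodes in no triangle have all-zero synergy rows
#' and receive only teleport-driven mass.
#'
#' @param net An `adn` object.
#' @inheritParams pagerank
#' @inheritParams motif_synergy
#' @return A `pagerank_scores` tibble; the `mpr_synergy` object used is
#'   attached as attribute `synergy`.
#' @examples
#' net <- fixture_networks()$planted30
#' head(dplyr::arrange(mpr_scores(net), dplyr::desc(score)), 3)
#' @export
mpr_scores <- function(net, damping = 0.85, tol = 1e-10, max_iter = 1000,
                       direction = c("increase", "decrease")) {
  syn <- synergy_matrix(net, direction = direction)
  out <- pagerank(transition_matrix(syn$S), damping, tol, max_iter)
  attr(out, "method") <- "mpr"
  attr(out, "synergy") <- syn
  out
}

#' Plain weighted PageRank node scores
#'
#' The binary-relation baseline: PageRank on the transition matrix built
#' from the raw co-occurrence weights `W` instead of the synergy matrix.
#'
#' @inheritParams mpr_scores
#' @return A `pagerank_scores` tibble.
#' @export
weighted_pagerank_scores <- function(net, damping = 0.85, tol = 1e-10,
                                     max_iter = 1000) {
  stopifnot(inherits(net, "adn"))
  out <- pagerank(transition_matrix(weight_matrix(net)), damping, tol, max_iter)
  attr(out, "method") <- "weighted-pagerank"
  out
}

#' @export
print.pagerank_scores <- function(x, ...) {
  cat(sprintf("# %s scores: %d nodes, d = %.2f, %d iterations (residual %.2g)\n",
              attr(x, "method"), nrow(x), attr(x, "damping"),
              attr(x, "iterations"), attr(x, "residual")))
  NextMethod()
  invisible(x)
}
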