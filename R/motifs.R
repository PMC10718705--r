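#' The 3-node motif pattern used for synergy attribution
#'
#' A motif on k nodes is a pair (B, A): B is the k x k binary adjacency
#' pattern and A the anchor index set. The default (and only built-in) motif
#' class is the closed triangle: all off-diagonal entries of B are 1 and all
#' three nodes are anchors. Open triads are deliberately excluded: the
#' synergy of a triple is attributed to each of its pairs, which is
#' ill-defined for the non-adjacent pair of an open triad.
#'
#' @return A list with the binary pattern matrix `B` and anchor set `A`.
#' @export
triangle_motif <- function() {
  B <- matrix(1, 3, 3) - diag(3)
  list(B = B, A = 1:3)
}

#' Enumerate 3-node motifs (closed triangles)
#'
#' Lists every unordered node triple whose three pairwise edges are all
#' present, each exactly once.
#'
#' @param net An `adn` object.
#' @return A tibble with columns `node_a`, `node_b`, `node_c`; within each
#'   row the codes are sorted, and rows are in lexicographic order.
#' @export
enumerate_motifs <- function(net) {
  stopifnot(inherits(net, "adn"))
  empty <- tibble::tibble(node_a = character(), node_b = character(),
                          node_c = character())
  if (nrow(net) == 0) return(empty)
  g <- adn_igraph(net)
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(empty)
  m <- matrix(igraph::V(g)$name[as.integer(tri)], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  out <- tibble::tibble(node_a = m[, 1], node_b = m[, 2], node_c = m[, 3])
  dplyr::arrange(out, .data$node_a, .data$node_b, .data$node_c)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

ei_from_matrix <- function(W) {
  s <- rowSums(W)
  keep <- which(s > 0)
  if (length(keep) == 0) return(0)
  P <- W[keep, , drop = FALSE] / s[keep]
  h <- apply(P, 1, entropy_bits)
  entropy_bits(colMeans(P)) - mean(h)
}

#' Effective information of a weighted network
#'
#' Treats each undirected edge as two directed edges of equal weight and
#' normalizes each node's out-weight vector into a probability distribution
#' over all N node positions. Effective information (EI) is the entropy of
#' the average out-distribution minus the average per-node entropy (base-2
#' logarithms, so the unit is bits):
#' \deqn{EI(G) = H(\langle W_i^{out} \rangle) - \langle H(W_i^{out}) \rangle.}
#' EI quantifies how distinctly nodes spread their connection weight: it is 0
#' exactly when all out-distributions are identical and grows as they
#' diverge. Nodes with zero out-strength (isolated nodes) are excluded from
#' both averages; a network with no edges has EI 0 by convention.
#'
#' @param net An `adn` object, or a nonnegative square weight matrix.
#' @return Effective information in bits (a single number; may be small but
#'   is not guaranteed nonnegative for arbitrary nonnegative matrices).
#' @examples
#' effective_information(fixture_networks()$star3)  # ~0.9183 bits
#' effective_information(fixture_networks()$k3)     # 0: identical profiles
#' @export
effective_information <- function(net) {
  W <- if (inherits(net, "adn")) weight_matrix(net) else as.matrix(net)
  if (nrow(W) != ncol(W) || any(W < 0)) {
    stop("`net` must be an adn object or a nonnegative square matrix",
         call. = FALSE)
  }
  ei_from_matrix(W)
}

#' Per-node out-weight profiles
#'
#' The normalized out-weight distribution and its entropy for every node
#' with positive out-strength, i.e. the ingredients of
#' [effective_information()].
#'
#' @param net An `adn` object.
#' @return A tibble with columns `node`, `entropy` (bits) and a list-column
#'   `distribution` (named probability vector over all N nodes).
#' @export
out_weight_profiles <- function(net) {
  W <- weight_matrix(net)
  s <- rowSums(W)
  keep <- which(s > 0)
  nodes <- rownames(W)[keep]
  dists <- lapply(keep, function(i) W[i, ] / s[i])
  tibble::tibble(
    node = nodes,
    entropy = vapply(dists, entropy_bits, numeric(1)),
    distribution = dists
  )
}

drop_triangle_edges <- function(W, i, j, k) {
  W[i, j] <- W[j, i] <- 0
  W[i, k] <- W[k, i] <- 0
  W[j, k] <- W[k, j] <- 0
  W
}

#' Synergy strength of one motif
#'
#' The synergistic strength of a 3-node motif is the change in the network's
#' effective information caused by deleting its three edges from a copy of
#' the network. Under the default `direction = "increase"` it is
#' \eqn{EI(G_i') - EI(G)}: a motif whose joint co-occurrence binds its
#' members into the network's shared connectivity keeps their out-profiles
#' broad and mutually similar, so dissolving it makes the profiles more
#' individually deterministic and EI rises — the size of that rise is the
#' triple's synergy. `direction = "decrease"` returns the negated value,
#' \eqn{EI(G) - EI(G_i')} (the EI drop on removal); on realistic
#' co-occurrence networks that quantity is negative for the vast majority
#' of triangles, which is why the increase convention is the default (see
#' the methods vignette). Nodes are never deleted; a node isolated by the
#' removal simply stops contributing to the EI averages. Either direction
#' may produce negative values.
#'
#' @param net An `adn` object.
#' @param motif A length-3 character vector of node codes, or a one-row
#'   slice of [enumerate_motifs()] output.
#' @param base_ei `effective_information(net)`, precomputed by the caller.
#' @param direction `"increase"` (default) or `"decrease"`; the two are
#'   exact negations of each other.
#' @return The motif's synergy strength in bits.
#' @export
motif_synergy <- function(net, motif, base_ei = effective_information(net),
                          direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(inherits(net, "adn"))
  if (is.data.frame(motif)) {
    stopifnot(nrow(motif) == 1)
    motif <- c(motif$node_a, motif$node_b, motif$node_c)
  }
  motif <- normalize_codes(motif)
  stopifnot(length(motif) == 3)
  W <- weight_matrix(net)
  idx <- match(motif, rownames(W))
  if (anyNA(idx)) {
    stop("motif node(s) not in network: ",
         paste(motif[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  prs <- utils::combn(3, 2)
  for (p in seq_len(ncol(prs))) {
    u <- idx[prs[1, p]]; v <- idx[prs[2, p]]
    if (W[u, v] <= 0) {
      stop("motif edge missing from network: ",
           motif[prs[1, p]], "--", motif[prs[2, p]], call. = FALSE)
    }
  }
  gain <- ei_from_matrix(drop_triangle_edges(W, idx[1], idx[2], idx[3])) -
    base_ei
  if (direction == "increase") gain else -gain
}

# Incremental EI over all triangles. Removing one triangle changes only the
# out-profiles of its three member rows, so EI(G') is recomputed from the
# maintained row entropies and column-sum vector instead of from scratch.
# With v = sum of contributing rows (each summing to 1) and m contributors,
# H(v/m) = log2(m) - (1/m) * sum(v * log2(v)).
synergy_deltas <- function(W, triangles, base_ei) {
  n <- nrow(W)
  s <- rowSums(W)
  P <- W / ifelse(s > 0, s, 1)
  P[s <= 0, ] <- 0
  h <- apply(P, 1, entropy_bits)
  contrib <- s > 0
  m0 <- sum(contrib)
  v0 <- colSums(P[contrib, , drop = FALSE])
  sum_h0 <- sum(h[contrib])
  vapply(seq_len(nrow(triangles)), function(t) {
    idx <- triangles[t, ]
    v <- v0
    m <- m0
    sum_h <- sum_h0
    wab <- W[idx[1], idx[2]]; wac <- W[idx[1], idx[3]]; wbc <- W[idx[2], idx[3]]
    loss <- c(wab + wac, wab + wbc, wac + wbc)
    for (q in 1:3) {
      i <- idx[q]
      if (!contrib[i]) next
      v <- v - P[i, ]
      m <- m - 1L
      sum_h <- sum_h - h[i]
      s_new <- s[i] - loss[q]
      if (s_new > 1e-12) {
        row <- W[i, ]
        row[idx] <- 0
        row <- row / s_new
        v <- v + row
        m <- m + 1L
        sum_h <- sum_h + entropy_bits(row)
      }
    }
    ei_new <- if (m == 0) 0 else {
      vp <- v[v > 1e-15]
      (log2(m) - sum(vp * log2(vp)) / m) - sum_h / m
    }
    ei_new - base_ei
  }, numeric(1))
}

#' Synergy-strength matrix of a network
#'
#' Enumerates all closed triangles, measures each one's synergy strength
#' ([motif_synergy()]: the effective-information change caused by removing
#' it), and aggregates per node pair:
#' \deqn{S(v_i, v_j) = \sum_{(v_i,v_j) \in \Delta_k} EI(\Delta_k),}
#' summing over every triangle that contains the pair. Negative per-motif
#' values are clamped to 0 in `S` (the downstream random-walk transition
#' matrix needs nonnegative weights) but are kept unclamped in the motif
#' table so the raw synergy distribution can be inspected and the clamping
#' decision audited.
#'
#' @param net An `adn` object.
#' @inheritParams motif_synergy
#' @return An object of class `mpr_synergy`: a list with `S` (symmetric
#'   nonnegative matrix with zero diagonal, named by [adn_nodes()]),
#'   `motifs` (tibble `node_a`, `node_b`, `node_c`, `ei_delta`, unclamped,
#'   signed per `direction`), and `ei_g` (the full network's EI in bits).
#' @export
synergy_matrix <- function(net, direction = c("increase", "decrease")) {
  stopifnot(inherits(net, "adn"))
  direction <- match.arg(direction)
  W <- weight_matrix(net)
  nodes <- rownames(W)
  motifs <- enumerate_motifs(net)
  base_ei <- ei_from_matrix(W)
  S <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  if (nrow(motifs) > 0) {
    tri_idx <- cbind(match(motifs$node_a, nodes),
                     match(motifs$node_b, nodes),
                     match(motifs$node_c, nodes))
    deltas <- synergy_deltas(W, tri_idx, base_ei)
    if (direction == "decrease") deltas <- -deltas
    motifs$ei_delta <- deltas
    clamped <- pmax(deltas, 0)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      ij <- tri_idx[, p, drop = FALSE]
      inc <- tapply(clamped, paste(ij[, 1], ij[, 2]), sum)
      uv <- do.call(rbind, lapply(strsplit(names(inc), " "), as.integer))
      S[uv] <- S[uv] + as.numeric(inc)
      S[uv[, 2:1, drop = FALSE]] <- S[uv[, 2:1, drop = FALSE]] + as.numeric(inc)
    }
  } else {
    motifs$ei_delta <- numeric(0)
  }
  structure(list(S = S, motifs = motifs, ei_g = base_ei,
                 direction = direction),
            class = "mpr_synergy")
}

#' @export
print.mpr_synergy <- function(x, ...) {
  cat(sprintf(
    "# Motif synergy: %d triangles on %d nodes; EI(G) = %.4f bits\n",
    nrow(x$motifs), nrow(x$S), x$ei_g))
  if (nrow(x$motifs) > 0) {
    cat(sprintf("# ei_delta range: [%.4g, %.4g]; %d negative value(s) clamped in S\n",
                min(x$motifs$ei_delta), max(x$motifs$ei_delta),
                sum(x$motifs$ei_delta < 0)))
  }
  invisible(x)
}

#' @export
as.matrix.mpr_synergy <- function(x, ...) x$S

#' Log-binned distribution of motif synergy strengths
#'
#' Bins the positive per-motif synergy values into logarithmically spaced
#' bins, the form in which a heavy-tailed (power-law-like) distribution is
#' inspected on log-log axes.
#'
#' @param synergy An `mpr_synergy` object or its motif table.
#' @param bins Number of bins; defaults to the number of distinct positive
#'   values, capped at 20.
#' @param path Optional TSV output path.
#' @return A tibble with columns `bin_center` (geometric bin center) and
#'   `probability` (empirical probability of the bin among positive values).
#'   All-zero/negative synergies yield an empty tibble with a warning.
#' @export
synergy_distribution <- function(synergy, bins = NULL, path = NULL) {
  tab <- if (inherits(synergy, "mpr_synergy")) synergy$motifs else synergy
  stopifnot(is.data.frame(tab), "ei_delta" %in% names(tab), nrow(tab) > 0)
  vals <- tab$ei_delta[tab$ei_delta > 0]
  if (length(vals) == 0) {
    warning("no positive synergy values; empty distribution", call. = FALSE)
    return(tibble::tibble(bin_center = numeric(), probability = numeric()))
  }
  if (is.null(bins)) bins <- min(20L, length(unique(vals)))
  lo <- min(vals); hi <- max(vals)
  if (hi / lo < 1 + 1e-12 || bins == 1) {
    out <- tibble::tibble(bin_center = lo, probability = 1)
  } else {
    breaks <- exp(seq(log(lo), log(hi), length.out = bins + 1))
    breaks[1] <- breaks[1] * (1 - 1e-9)
    breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-9)
    cut_idx <- cut(vals, breaks = breaks, labels = FALSE)
    centers <- sqrt(breaks[-length(breaks)] * breaks[-1])
    cnt <- tabulate(cut_idx, nbins = bins)
    keep <- cnt > 0
    out <- tibble::tibble(bin_center = centers[keep],
                          probability = cnt[keep] / length(vals))
  }
  if (!is.null(path)) {
    utils::write.table(as.data.frame(out), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  out
}
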