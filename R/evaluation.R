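score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    nm <- intersect(c("score", "influence"), names(scores))
    stopifnot("node" %in% names(scores), length(nm) >= 1)
    stats::setNames(scores[[nm[1]]], scores$node)
  } else {
    stopifnot(is.numeric(scores))
    scores
  }
}

#' Ranking resolution
#'
#' Measures how finely a scoring separates nodes into distinct score
#' classes: \deqn{f(r_A) = 1 - \sum_{i=1}^{R} N_i^2 / (R N^2),} where R is
#' the number of distinct score classes and N_i their sizes. A constant
#' ranking (R = 1) gives exactly 0 — the scorer cannot distinguish any
#' nodes — and the maximum 1 - 1/N^2 is reached when all scores differ.
#' Score classes are formed by grouping values equal after rounding.
#'
#' @param scores Named numeric vector or a tibble with `node` and `score`
#'   (or `influence`) columns.
#' @param digits Rounding precision used to group scores into classes
#'   (default 6 decimals).
#' @return Resolution in `[0, 1 - 1/N^2]`.
#' @examples
#' resolution(c(a = 1, b = 1, c = 1))        # 0
#' resolution(c(a = 1, b = 2, c = 3, d = 4)) # 0.9375
#' @export
resolution <- function(scores, digits = 6) {
  x <- score_vector(scores)
  n <- length(x)
  if (n == 0) stop("resolution of an empty ranking is undefined", call. = FALSE)
  sizes <- as.numeric(table(round(x, digits)))
  r <- length(sizes)
  1 - sum(sizes^2) / (r * n^2)
}

#' Network efficiency after node removal
#'
#' Deletes the given nodes (and incident edges) from a copy of the network
#' and evaluates, on the N' remaining nodes, the mean pairwise inverse
#' shortest-path distance \eqn{\eta = \frac{1}{N'(N'-1)} \sum_{i \ne j}
#' 1/d_{ij}} with hop-count distances and \eqn{1/\infty = 0} for
#' disconnected pairs (the global-efficiency form). The lower the efficiency
#' after removing a candidate key-node set, the stronger those nodes'
#' bridging role. `form = "literal"` instead returns the plain mean of the
#' distances themselves, \eqn{\frac{1}{N'(N'-1)} \sum d_{ij}}, which is
#' infinite when the remainder is disconnected.
#'
#' @param net An `adn` object.
#' @param removed Character vector of nodes to delete (must be a subset of
#'   the node set). Default: none.
#' @param form `"reciprocal"` (default) or `"literal"`.
#' @param distance `"hop"` (default; each edge counts 1) or
#'   `"inverse-weight"` (edge length 1/weight, treating heavy co-occurrence
#'   as proximity).
#' @return A single nonnegative number; 0 when fewer than 2 nodes remain.
#' @export
network_efficiency <- function(net, removed = character(),
                               form = c("reciprocal", "literal"),
                               distance = c("hop", "inverse-weight")) {
  stopifnot(inherits(net, "adn"))
  form <- match.arg(form)
  distance <- match.arg(distance)
  removed <- normalize_codes(removed)
  if (!all(removed %in% adn_nodes(net))) {
    stop("removed node(s) not in network: ",
         paste(setdiff(removed, adn_nodes(net)), collapse = ", "),
         call. = FALSE)
  }
  g <- adn_igraph(net)
  if (length(removed) > 0) g <- igraph::delete_vertices(g, removed)
  np <- igraph::vcount(g)
  if (np < 2) return(0)
  w <- if (distance == "hop") NA else 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = w)
  off <- d[row(d) != col(d)]
  if (form == "reciprocal") {
    mean(ifelse(is.infinite(off), 0, 1 / off))
  } else {
    mean(off)
  }
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Weighted-cascade influence benchmark
#'
#' The ground-truth scoring against which rankings are judged. The
#' undirected network is directionalized (each edge becomes two directed
#' edges) and each directed edge gets the activation probability
#' \eqn{p_{ij} = W_{ij} / \sum_{v_k \in N_i} W_{ik}} — the source's
#' out-weight share. For every node used as the sole seed, an independent
#' cascade is simulated (each newly activated node gets one chance to
#' activate each inactive out-neighbor with probability p); the node's
#' influence is the number of other nodes activated, averaged over `runs`
#' repetitions. The benchmark deliberately runs on the raw weight matrix W,
#' independent of any scorer under test. Fully reproducible from `seed`.
#'
#' @param net An `adn` object.
#' @param runs Cascade repetitions per seed node (default 10).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `node`, `influence` (mean cascade size in
#'   `[0, N-1]`; isolated nodes score 0), with `runs` and `seed` attributes.
#' @export
wc_benchmark <- function(net, runs = 10, seed = 1) {
  stopifnot(inherits(net, "adn"), runs >= 1)
  W <- weight_matrix(net)
  nodes <- rownames(W)
  n <- length(nodes)
  s <- rowSums(W)
  nbrs <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  probs <- lapply(seq_len(n), function(i) {
    if (s[i] > 0) W[i, nbrs[[i]]] / s[i] else numeric(0)
  })
  influence <- with_seed(seed, {
    vapply(seq_len(n), function(src) {
      total <- 0
      for (r in seq_len(runs)) {
        active <- logical(n)
        active[src] <- TRUE
        frontier <- src
        while (length(frontier) > 0) {
          newly <- integer(0)
          for (u in frontier) {
            cand <- nbrs[[u]]
            cand_inactive <- cand[!active[cand]]
            if (length(cand_inactive) == 0) next
            p <- probs[[u]][!active[cand]]
            hit <- cand_inactive[stats::runif(length(cand_inactive)) < p]
            if (length(hit) > 0) {
              active[hit] <- TRUE
              newly <- c(newly, hit)
            }
          }
          frontier <- newly
        }
        total <- total + (sum(active) - 1)
      }
      total / runs
    }, numeric(1))
  })
  structure(tibble::tibble(node = nodes, influence = influence),
            runs = runs, seed = seed,
            class = c("wc_influence", class(tibble::tibble())))
}

#' Kendall rank-correlation accuracy against a benchmark
#'
#' Kendall correlation between a scorer's values and the weighted-cascade
#' benchmark influences over the same node set. The tie-corrected tau-b is
#' reported by default (ties are pervasive in centrality scores); the plain
#' tau-a form \eqn{\tau = 2(X_a - X_b) / (X(X-1))}, with \eqn{X_a}
#' concordant and \eqn{X_b} discordant pairs over X items, is available via
#' `variant = "tau-a"`.
#'
#' @param scores Named numeric vector, or tibble with `node` and `score`.
#' @param benchmark Same shapes accepted (e.g. [wc_benchmark()] output).
#' @param variant `"tau-b"` (default) or `"tau-a"`.
#' @return Correlation in `[-1, 1]`.
#' @export
kendall_accuracy <- function(scores, benchmark, variant = c("tau-b", "tau-a")) {
  variant <- match.arg(variant)
  x <- score_vector(scores)
  y <- score_vector(benchmark)
  if (is.null(names(x)) || is.null(names(y))) {
    stopifnot(length(x) == length(y))
  } else {
    if (!setequal(names(x), names(y))) {
      stop("`scores` and `benchmark` must cover the same node set", call. = FALSE)
    }
    y <- y[names(x)]
  }
  n <- length(x)
  if (n < 2) stop("Kendall correlation needs at least 2 nodes", call. = FALSE)
  if (variant == "tau-b") {
    return(stats::cor(x, y, method = "kendall"))
  }
  sgn <- 0
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  ut <- upper.tri(dx)
  sgn <- sum(sign(dx[ut]) * sign(dy[ut]))
  2 * sgn / (n * (n - 1))
}

#' Baseline centralities on the unweighted topology
#'
#' Standard centralities used as comparison scorers: closeness (reciprocal
#' of the average shortest-path distance to the reachable nodes),
#' betweenness (sum of the fractions of all-pairs shortest paths through the
#' node), eigenvector centrality, and (un)weighted degree. Computed on the
#' unweighted topology by default, since edge weights here are co-occurrence
#' counts, not distances.
#'
#' @param net An `adn` object.
#' @param method One of `"closeness"`, `"betweenness"`, `"eigenvector"`,
#'   `"degree"`, `"weighted-degree"`.
#' @return A tibble with columns `node`, `score`.
#' @export
baseline_centrality <- function(net,
                                method = c("closeness", "betweenness",
                                           "eigenvector", "degree",
                                           "weighted-degree")) {
  stopifnot(inherits(net, "adn"))
  method <- match.arg(method)
  g <- adn_igraph(net)
  if (method == "eigenvector" && nrow(net) == 0) {
    stop("eigenvector centrality is undefined on an edgeless network",
         call. = FALSE)
  }
  score <- switch(method,
    closeness = {
      cl <- suppressWarnings(igraph::closeness(g, weights = NA,
                                               normalized = TRUE))
      ifelse(is.nan(cl) | is.na(cl), 0, cl)
    },
    betweenness = igraph::betweenness(g, weights = NA),
    eigenvector = igraph::eigen_centrality(g, weights = NA)$vector,
    degree = igraph::degree(g),
    `weighted-degree` = igraph::strength(g)
  )
  tibble::tibble(node = igraph::V(g)$name, score = as.numeric(score))
}

#' Empirical complementary cumulative distribution function
#'
#' For each distinct score value x, the fraction of scores that are at
#' least x; the curve used to compare how widely scorers spread their
#' values.
#'
#' @param scores Numeric vector or tibble with a `score` column.
#' @return A tibble (`score`, `ccdf`), scores ascending, `ccdf`
#'   non-increasing and starting at 1.
#' @export
ccdf <- function(scores) {
  x <- score_vector(scores)
  stopifnot(length(x) > 0)
  vals <- sort(unique(x))
  tibble::tibble(
    score = vals,
    ccdf = vapply(vals, function(v) mean(x >= v), numeric(1))
  )
}

scorer_registry <- function() {
  list(
    "mpr" = function(net, ...) mpr_scores(net, ...),
    "weighted-pagerank" = function(net, ...) weighted_pagerank_scores(net, ...),
    "closeness" = function(net, ...) baseline_centrality(net, "closeness"),
    "betweenness" = function(net, ...) baseline_centrality(net, "betweenness"),
    "eigenvector" = function(net, ...) baseline_centrality(net, "eigenvector"),
    "degree" = function(net, ...) baseline_centrality(net, "degree"),
    "weighted-degree" = function(net, ...) baseline_centrality(net, "weighted-degree"),
    "constant" = function(net, ...) tibble::tibble(node = adn_nodes(net), score = 1)
  )
}

#' Score a network with a named algorithm
#'
#' Dispatch helper over the built-in scorers: `"mpr"`,
#' `"weighted-pagerank"`, `"closeness"`, `"betweenness"`, `"eigenvector"`,
#' `"degree"`, `"weighted-degree"`, and the degenerate `"constant"` scorer
#' (every node scored 1; useful as a resolution floor).
#'
#' @param net An `adn` object.
#' @param algorithm Scorer name.
#' @param ... Passed to PageRank-based scorers (`damping`, `tol`, ...).
#' @return A tibble with columns `node`, `score`.
#' @export
score_network <- function(net, algorithm = "mpr", ...) {
  reg <- scorer_registry()
  if (!algorithm %in% names(reg)) {
    stop("unknown algorithm ", sQuote(algorithm), "; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[algorithm]](net, ...)
}

#' Evaluate scorers on resolution, efficiency and cascade accuracy
#'
#' For each algorithm: (1) the resolution of its full ranking; (2) the
#' network efficiency after removing its selected key nodes (union of the
#' top-k per community, mirroring how key acupoints are reported); (3) the
#' Kendall accuracy of its scores against the weighted-cascade benchmark.
#' The benchmark is simulated once and shared across algorithms.
#'
#' @param net An `adn` object.
#' @param algorithms Character vector of scorer names (see
#'   [score_network()]).
#' @param partition Community partition for key-node selection.
#' @param k Key nodes per community (default 3).
#' @param runs Weighted-cascade repetitions (default 10).
#' @param seed RNG seed for the benchmark.
#' @param ... Passed to the scorers.
#' @return An `adn_evaluation` tibble: one row per algorithm with columns
#'   `algorithm`, `resolution`, `efficiency`, `accuracy`, plus a `removed`
#'   list-column of the key nodes each algorithm selected.
#' @export
evaluate_all <- function(net,
                         algorithms = c("mpr", "weighted-pagerank",
                                        "closeness", "betweenness",
                                        "eigenvector"),
                         partition = default_partition(), k = 3,
                         runs = 10, seed = 1, ...) {
  stopifnot(inherits(net, "adn"))
  bench <- wc_benchmark(net, runs = runs, seed = seed)
  rows <- lapply(algorithms, function(alg) {
    sc <- score_network(net, alg, ...)
    report <- top_k_per_community(sc, partition, k)
    removed <- unique(report$node)
    tibble::tibble(
      algorithm = alg,
      resolution = resolution(sc),
      efficiency = network_efficiency(net, removed),
      accuracy = kendall_accuracy(sc, bench),
      removed = list(removed)
    )
  })
  structure(dplyr::bind_rows(rows),
            k = k, runs = runs, seed = seed,
            class = c("adn_evaluation", class(tibble::tibble())))
}
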