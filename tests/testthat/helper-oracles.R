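# Independent brute-force oracles used across the suites. These deliberately
# re-derive every quantity with naive loops, never via the package's own
# internals.

# pairwise co-occurrence counts by double loop over records and pairs
oracle_cooccurrence <- function(sets) {
  items <- sort(unique(unlist(sets)))
  counts <- list()
  for (s in sets) {
    s <- sort(unique(s))
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      for (j in seq(i + 1, length(s))) {
        key <- paste(s[i], s[j], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive triple scan for closed triangles
oracle_triangles <- function(net) {
  W <- weight_matrix(net)
  nodes <- rownames(W)
  if (length(nodes) < 3) return(character(0))
  out <- character(0)
  idx <- utils::combn(length(nodes), 3)
  for (c_i in seq_len(ncol(idx))) {
    t <- idx[, c_i]
    if (W[t[1], t[2]] > 0 && W[t[1], t[3]] > 0 && W[t[2], t[3]] > 0) {
      out <- c(out, paste(nodes[t], collapse = "|"))
    }
  }
  sort(out)
}

# effective information re-derived with plain loops
oracle_ei <- function(W) {
  n <- nrow(W)
  rows <- list()
  ents <- numeric(0)
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s <= 0) next
    p <- W[i, ] / s
    h <- 0
    for (x in p) if (x > 0) h <- h - x * log2(x)
    rows[[length(rows) + 1]] <- p
    ents <- c(ents, h)
  }
  if (length(rows) == 0) return(0)
  avg <- Reduce(`+`, rows) / length(rows)
  h_avg <- 0
  for (x in avg) if (x > 0) h_avg <- h_avg - x * log2(x)
  h_avg - mean(ents)
}

# stationary PageRank by dense linear solve of x = d P^T x + (1-d)/n
oracle_pagerank <- function(P, d = 0.85) {
  n <- nrow(P)
  x <- solve(diag(n) - d * t(P), rep((1 - d) / n, n))
  x / sum(x)
}

# hop-count BFS distances from one source over an adjacency list
oracle_bfs <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_adjlist <- function(net, removed = character()) {
  nodes <- setdiff(adn_nodes(net), removed)
  W <- weight_matrix(net)
  W <- W[nodes, nodes, drop = FALSE]
  lapply(seq_along(nodes), function(i) which(W[i, ] > 0))
}

# global efficiency after node removal via all-pairs BFS
oracle_efficiency <- function(net, removed = character()) {
  adj <- oracle_adjlist(net, removed)
  n <- length(adj)
  if (n < 2) return(0)
  tot <- 0
  for (s in seq_len(n)) {
    d <- oracle_bfs(adj, s)
    for (t in seq_len(n)) {
      if (t != s && is.finite(d[t])) tot <- tot + 1 / d[t]
    }
  }
  tot / (n * (n - 1))
}

# Kendall tau by exhaustive pair counting (tau-a and tie-corrected tau-b)
oracle_kendall <- function(x, y, variant = "tau-b") {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sign(x[i] - x[j])
      b <- sign(y[i] - y[j])
      if (a == 0 && b == 0) {
        tx <- tx + 1; ty <- ty + 1
      } else if (a == 0) {
        tx <- tx + 1
      } else if (b == 0) {
        ty <- ty + 1
      } else if (a == b) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  if (variant == "tau-a") {
    2 * (conc - disc) / (n * (n - 1))
  } else {
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  }
}

# seeded Erdos-Renyi-style weighted test network
random_test_network <- function(n, p = 0.3, seed = 1, max_w = 4) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < p
  edges <- tibble::tibble(
    from = nodes[idx[1, keep]],
    to = nodes[idx[2, keep]],
    weight = sample(seq_len(max_w), sum(keep), replace = TRUE)
  )
  as_adn(edges, nodes = nodes)
}

random_records <- function(n_records, items, min_k = 1, max_k = 5, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_records), function(i) {
    sample(items, sample(seq(min_k, min(max_k, length(items))), 1))
  })
  names(sets) <- sprintf("D%03d", seq_len(n_records))
  sets
}
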