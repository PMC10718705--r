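test_that("resolution follows the class-size formula", {
  expect_equal(resolution(c(a = 1, b = 1, c = 1)), 0)
  expect_equal(resolution(c(1, 2, 3, 4)), 1 - 4 / (4 * 16))
  expect_equal(resolution(c(1, 1, 2, 2)), 1 - 8 / (2 * 16))
  expect_error(resolution(numeric(0)), "empty")
})

test_that("resolution is bounded and maximal iff all scores are distinct", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)
    f <- resolution(x)
    expect_gte(f, 0)
    expect_lte(f, 1 - 1 / n^2 + 1e-12)
    if (length(unique(x)) == n) expect_equal(f, 1 - 1 / n^2)
  }
  expect_equal(resolution(stats::runif(10)), 1 - 1 / 100)
  # rounding precision groups near-equal scores
  expect_equal(resolution(c(0.1234567, 0.1234568), digits = 6), 0)
})

test_that("network efficiency matches definitions on known graphs", {
  fx <- fixture_networks()
  expect_equal(network_efficiency(fx$k3), 1)
  expect_equal(network_efficiency(fx$path3, removed = "B"), 0)
  expect_equal(network_efficiency(fx$path3),
               (4 * 1 + 2 * 0.5) / 6)  # pairs at distance 1,1,2
  expect_equal(network_efficiency(fx$k3, removed = c("A", "B")), 0)
  expect_error(network_efficiency(fx$k3, removed = "Q"), "not in network")
})

test_that("efficiency after removal equals an all-pairs BFS recomputation", {
  net <- random_test_network(15, p = 0.25, seed = 31)
  sc <- baseline_centrality(net, "degree")
  top3 <- sc$node[order(-sc$score)][1:3]
  expect_equal(network_efficiency(net, removed = top3),
               oracle_efficiency(net, removed = top3), tolerance = 1e-12)
  expect_equal(network_efficiency(net), oracle_efficiency(net),
               tolerance = 1e-12)
})

test_that("the literal efficiency form averages raw distances", {
  fx <- fixture_networks()
  expect_equal(network_efficiency(fx$path3, form = "literal"),
               (4 * 1 + 2 * 2) / 6)
  # disconnection makes the literal form infinite, the reciprocal form finite
  two <- as_adn(tibble::tibble(from = c("a", "c"), to = c("b", "d"), weight = 1))
  expect_equal(network_efficiency(two, form = "literal"), Inf)
  expect_equal(network_efficiency(two), (4 * 1) / 12)
})

test_that("removing a superset never increases the connected-pair count", {
  net <- random_test_network(15, p = 0.2, seed = 32)
  pair_count <- function(removed) {
    adj <- oracle_adjlist(net, removed)
    n <- length(adj)
    if (n < 2) return(0)
    sum(vapply(seq_len(n),
               function(s) sum(is.finite(oracle_bfs(adj, s))) - 1, numeric(1)))
  }
  r1 <- adn_nodes(net)[1:2]
  r2 <- adn_nodes(net)[1:5]
  expect_gte(pair_count(r1), pair_count(r2))
})

test_that("weighted-cascade scores respect certain and impossible cascades", {
  net <- build_adn(list(D1 = c("a", "b"), D2 = "z"))
  sc <- wc_benchmark(net, runs = 5, seed = 1)
  inf <- stats::setNames(sc$influence, sc$node)
  expect_equal(unname(inf["Z"]), 0)       # isolated node influences nobody
  expect_equal(unname(inf["A"]), 1)       # sole neighbor activates w.p. 1
  expect_equal(unname(inf["B"]), 1)
})

test_that("weighted-cascade influence matches its closed-form expectation", {
  star <- fixture_networks()$star3
  sc <- wc_benchmark(star, runs = 10000, seed = 7)
  inf <- stats::setNames(sc$influence, sc$node)
  # center: two leaves activated independently w.p. 1/2 each -> mean 1.0
  se <- sqrt(0.5) / sqrt(10000)
  expect_lt(abs(inf["C"] - 1), 3 * se)
  # leaf: center certain, then far leaf w.p. 1/2 -> mean 1.5
  expect_lt(abs(inf["L1"] - 1.5), 3 * sqrt(0.25) / sqrt(10000))
})

test_that("weighted-cascade scores are reproducible from the seed", {
  net <- random_test_network(12, p = 0.3, seed = 3)
  a <- wc_benchmark(net, runs = 20, seed = 123)
  b <- wc_benchmark(net, runs = 20, seed = 123)
  expect_identical(a$influence, b$influence)
  c <- wc_benchmark(net, runs = 20, seed = 124)
  expect_false(identical(a$influence, c$influence))
})

test_that("kendall accuracy matches exhaustive pair counting", {
  expect_equal(kendall_accuracy(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3)), 1)
  expect_equal(kendall_accuracy(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1)), -1)
  set.seed(5)
  x <- sample(1:6, 15, replace = TRUE)  # plenty of ties
  y <- sample(1:6, 15, replace = TRUE)
  expect_equal(kendall_accuracy(x, y), oracle_kendall(x, y, "tau-b"),
               tolerance = 1e-12)
  expect_equal(kendall_accuracy(x, y, variant = "tau-a"),
               oracle_kendall(x, y, "tau-a"), tolerance = 1e-12)
  expect_error(kendall_accuracy(c(a = 1), c(a = 2)), "at least 2")
})

test_that("kendall accuracy is symmetric and aligns nodes by name", {
  x <- c(a = 1, b = 3, c = 2)
  y <- c(c = 5, a = 1, b = 4)
  expect_equal(kendall_accuracy(x, y), kendall_accuracy(y, x))
  expect_equal(kendall_accuracy(x, x), 1)
  expect_error(kendall_accuracy(x, c(a = 1, b = 2, d = 3)), "same node set")
})

test_that("baseline centralities behave on canonical graphs", {
  star <- as_adn(tibble::tibble(from = "HUB", to = paste0("L", 1:5), weight = 1))
  for (m in c("closeness", "betweenness")) {
    sc <- baseline_centrality(star, m)
    expect_equal(sc$node[which.max(sc$score)], "HUB")
  }
  c6 <- as_adn(tibble::tibble(from = sprintf("n%d", 1:6),
                              to = sprintf("n%d", c(2:6, 1)), weight = 1))
  for (m in c("closeness", "betweenness", "eigenvector")) {
    sc <- baseline_centrality(c6, m)
    expect_equal(max(sc$score) - min(sc$score), 0, tolerance = 1e-9)
  }
  empty <- as_adn(tibble::tibble(from = character(), to = character(),
                                 weight = numeric()), nodes = c("a", "b"))
  expect_error(baseline_centrality(empty, "eigenvector"), "edgeless")
})

test_that("betweenness and closeness match brute-force path counting", {
  net <- random_test_network(12, p = 0.3, seed = 41)
  adj <- oracle_adjlist(net)
  nodes <- adn_nodes(net)
  n <- length(nodes)
  dist <- t(vapply(seq_len(n), function(s) oracle_bfs(adj, s), numeric(n)))
  # number of shortest paths between every pair by BFS DP
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    for (d in sort(unique(dist[s, is.finite(dist[s, ])]))) {
      for (v in which(dist[s, ] == d)) {
        if (d == 0) next
        preds <- adj[[v]][dist[s, adj[[v]]] == d - 1]
        nsp[s, v] <- sum(nsp[s, preds])
      }
    }
  }
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (s == v || t == v || !is.finite(dist[s, t])) next
      if (dist[s, v] + dist[v, t] == dist[s, t]) {
        tot <- tot + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
    tot
  }, numeric(1))
  got_b <- baseline_centrality(net, "betweenness")
  expect_equal(got_b$score, btw, tolerance = 1e-9)
  sumd <- vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    sum(d[is.finite(d)])
  }, numeric(1))
  got_c <- baseline_centrality(net, "closeness")
  # compare rankings: closeness orders inversely to total distance
  expect_equal(order(-got_c$score), order(sumd))
})

test_that("ccdf starts at one and matches direct counting", {
  got <- ccdf(c(1, 2, 3))
  expect_equal(got$ccdf, c(1, 2 / 3, 1 / 3))
  expect_equal(ccdf(rep(4, 5))$ccdf, 1)
  set.seed(8)
  x <- sample(1:5, 30, replace = TRUE)
  got <- ccdf(x)
  expect_equal(got$ccdf,
               vapply(got$score, function(v) sum(x >= v) / 30, numeric(1)))
  expect_true(all(diff(got$ccdf) <= 0))
})

test_that("evaluate_all composes the individual metrics", {
  net <- random_test_network(10, p = 0.5, seed = 51)
  ev <- suppressWarnings(evaluate_all(net, algorithms = c("degree", "degree", "closeness"),
                     runs = 10, seed = 9))
  expect_equal(ev[1, -1], ev[2, -1])  # identical algorithms, identical rows
  sc <- baseline_centrality(net, "degree")
  expect_equal(ev$resolution[1], resolution(sc))
  removed <- unique(suppressWarnings(top_k_per_community(sc, k = 3))$node)
  expect_equal(ev$efficiency[1], network_efficiency(net, removed))
  bench <- wc_benchmark(net, runs = 10, seed = 9)
  expect_equal(ev$accuracy[1], kendall_accuracy(sc, bench))
  expect_error(suppressWarnings(evaluate_all(net, algorithms = "nope")), "unknown algorithm")
})

test_that("MPR resolution exceeds a constant scorer on synthetic networks", {
  cfg <- generator_config(seed = 77)
  net <- build_adn(generate_records(cfg))
  expect_gt(resolution(mpr_scores(net)),
            resolution(score_network(net, "constant")))
})
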