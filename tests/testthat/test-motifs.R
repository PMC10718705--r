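test_that("triangle enumeration matches known counts and the motif pattern", {
  fx <- fixture_networks()
  expect_equal(nrow(enumerate_motifs(fx$k4)), 4)
  expect_equal(nrow(enumerate_motifs(fx$path3)), 0)
  expect_equal(nrow(enumerate_motifs(fx$k3)), 1)
  pat <- triangle_motif()
  expect_equal(pat$B, matrix(1, 3, 3) - diag(3))
  expect_equal(pat$A, 1:3)
})

test_that("triangle enumeration equals exhaustive scan and trace(A^3)/6", {
  for (seed in 1:3) {
    net <- random_test_network(20, p = 0.25, seed = seed)
    tri <- enumerate_motifs(net)
    keys <- sort(paste(tri$node_a, tri$node_b, tri$node_c, sep = "|"))
    expect_equal(keys, oracle_triangles(net))
    A <- (weight_matrix(net) > 0) * 1
    expect_equal(nrow(tri), sum(diag(A %*% A %*% A)) / 6)
  }
})

test_that("effective information matches hand-computed entropies", {
  fx <- fixture_networks()
  # star: mean vector (2/3, 1/6, 1/6); mean node entropy 1/3
  star_ei <- -(2 / 3 * log2(2 / 3) + 2 * (1 / 6) * log2(1 / 6)) - 1 / 3
  expect_equal(effective_information(fx$star3), star_ei, tolerance = 1e-12)
  expect_equal(round(star_ei, 4), 0.9183)
  # K3: rows are permutations of (0, 1/2, 1/2); mean vector uniform
  expect_equal(effective_information(fx$k3), log2(3) - 1, tolerance = 1e-12)
})

test_that("vertex-transitive unit-weight graphs have closed-form EI", {
  # out-profiles are permutations of one another, so the mean profile is
  # uniform over N positions while each row is uniform over its k neighbors:
  # EI = log2(N) - log2(k)
  c5 <- as_adn(tibble::tibble(from = paste0("n", 1:5),
                              to = paste0("n", c(2:5, 1)), weight = 1))
  expect_equal(effective_information(c5), log2(5) - 1, tolerance = 1e-12)
  expect_equal(effective_information(fixture_networks()$k4), 2 - log2(3),
               tolerance = 1e-12)
})

test_that("EI is zero exactly for identical out-profiles, else positive", {
  # identical rows are only possible for general (directed) weight matrices
  M <- matrix(c(1, 2, 1,
                1, 2, 1,
                1, 2, 1), 3, 3, byrow = TRUE)
  expect_equal(effective_information(M), 0)
  # any undirected network with an edge has non-identical profiles: EI > 0
  expect_gt(effective_information(fixture_networks()$star3), 0)
  expect_gt(effective_information(fixture_networks()$k3), 0)
  expect_gt(effective_information(random_test_network(10, seed = 3)), 0)
})

test_that("EI is invariant to uniform weight rescaling and matches the oracle", {
  net <- random_test_network(15, p = 0.3, seed = 11)
  W <- weight_matrix(net)
  expect_equal(effective_information(W), oracle_ei(W), tolerance = 1e-12)
  expect_equal(effective_information(W), effective_information(W * 7.5),
               tolerance = 1e-12)
  expect_equal(effective_information(matrix(0, 4, 4)), 0)
})

test_that("motif synergy equals from-scratch recomputation of both EIs", {
  net <- fixture_networks()$triangle_pendants
  base <- effective_information(net)
  tri <- enumerate_motifs(net)
  got <- motif_synergy(net, tri[1, ], base)
  W <- weight_matrix(net)
  Wd <- W
  for (p in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
    Wd[p[1], p[2]] <- Wd[p[2], p[1]] <- 0
  }
  expect_equal(got, oracle_ei(Wd) - oracle_ei(W), tolerance = 1e-12)
  # direction flag is an exact negation
  expect_equal(motif_synergy(net, tri[1, ], base, direction = "decrease"),
               -got, tolerance = 1e-15)
})

test_that("removing the only triangle of K3 empties the network", {
  # the edgeless remainder has EI 0 by convention, so the synergy is the
  # negated EI of K3 itself
  k3 <- fixture_networks()$k3
  expect_equal(motif_synergy(k3, c("A", "B", "C")), -(log2(3) - 1),
               tolerance = 1e-12)
})

test_that("motif synergy is a pure function and validates its motif", {
  net <- fixture_networks()$triangle_pendants
  before <- tidy(net)
  invisible(motif_synergy(net, c("A", "B", "D")))
  expect_equal(tidy(net), before)
  expect_error(motif_synergy(net, c("A", "B", "E")), "edge missing")
  expect_error(motif_synergy(net, c("A", "B", "Q")), "not in network")
})

test_that("deleting and re-adding an edge set restores EI exactly", {
  net <- random_test_network(12, p = 0.4, seed = 2)
  W <- weight_matrix(net)
  ei0 <- effective_information(W)
  W2 <- W
  W2[1, 2] <- W2[2, 1] <- 0
  W2[1, 2] <- W2[2, 1] <- W[1, 2]
  expect_identical(effective_information(W2), ei0)
})

test_that("synergy matrix is zero on triangle-free networks", {
  syn <- synergy_matrix(fixture_networks()$path3)
  expect_true(all(syn$S == 0))
  expect_equal(nrow(syn$motifs), 0)
})

test_that("a single positive-synergy triangle fills exactly three pairs", {
  net <- fixture_networks()$triangle_pendants
  syn <- synergy_matrix(net)
  s_val <- syn$motifs$ei_delta[1]
  expect_gt(s_val, 0)
  S <- syn$S
  expect_equal(sum(S[upper.tri(S)] > 0), 3)
  expect_equal(unname(S["A", "B"]), s_val)
  expect_equal(unname(S["A", "D"]), s_val)
  expect_equal(unname(S["B", "D"]), s_val)
})

test_that("synergy matrix equals brute-force per-pair summation", {
  net <- random_test_network(30, p = 0.2, seed = 4)
  syn <- synergy_matrix(net)
  base <- oracle_ei(weight_matrix(net))
  # independent route: enumerate triples exhaustively, recompute each EI
  # delta from scratch, sum clamped values per pair
  keys <- oracle_triangles(net)
  S2 <- syn$S * 0
  W <- weight_matrix(net)
  deltas <- numeric(0)
  for (k in keys) {
    t <- strsplit(k, "|", fixed = TRUE)[[1]]
    Wd <- W
    for (p in list(t[c(1, 2)], t[c(1, 3)], t[c(2, 3)])) {
      Wd[p[1], p[2]] <- Wd[p[2], p[1]] <- 0
    }
    d <- oracle_ei(Wd) - base
    deltas <- c(deltas, d)
    d <- max(d, 0)
    for (p in list(t[c(1, 2)], t[c(1, 3)], t[c(2, 3)])) {
      S2[p[1], p[2]] <- S2[p[1], p[2]] + d
      S2[p[2], p[1]] <- S2[p[2], p[1]] + d
    }
  }
  expect_equal(syn$S, S2, tolerance = 1e-9)
  expect_equal(sort(syn$motifs$ei_delta), sort(deltas), tolerance = 1e-9)
})

test_that("synergy aggregation identity holds on generated networks", {
  for (seed in c(3, 8)) {
    net <- random_test_network(25, p = 0.25, seed = seed)
    syn <- synergy_matrix(net)
    S <- syn$S
    expect_equal(S, t(S))
    expect_true(all(diag(S) == 0))
    expect_equal(sum(S[upper.tri(S)]),
                 3 * sum(pmax(syn$motifs$ei_delta, 0)),
                 tolerance = 1e-9)
  }
})

test_that("synergy directions are exact negations across the motif table", {
  net <- random_test_network(15, p = 0.35, seed = 6)
  up <- synergy_matrix(net, direction = "increase")
  dn <- synergy_matrix(net, direction = "decrease")
  expect_equal(up$motifs$ei_delta, -dn$motifs$ei_delta, tolerance = 1e-15)
})

test_that("synergy distribution bins log-spaced probabilities", {
  tab <- tibble::tibble(node_a = "a", node_b = "b", node_c = "c",
                        ei_delta = c(1, 1, 2, 4))
  dist <- synergy_distribution(tab)
  expect_equal(dist$probability, c(0.5, 0.25, 0.25))
  expect_equal(sum(dist$probability), 1)
  one <- synergy_distribution(tab[3, ])
  expect_equal(one$probability, 1)
  expect_warning(
    empty <- synergy_distribution(tibble::tibble(ei_delta = c(0, -1))),
    "no positive"
  )
  expect_equal(nrow(empty), 0)
})

test_that("default synthetic synergy distribution is heavy-tailed", {
  cfg <- generator_config(seed = 202)
  net <- build_adn(generate_records(cfg))
  syn <- synergy_matrix(net)
  dist <- synergy_distribution(syn, bins = 8)
  # heavy upper tail: past the modal bin the mass is monotone non-increasing,
  # and the largest synergies are rare
  k <- nrow(dist)
  mode_bin <- which.max(dist$probability)
  expect_lt(mode_bin, k)
  expect_true(all(diff(dist$probability[mode_bin:k]) <= 1e-12))
  expect_lt(dist$probability[k], 0.05)
})
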