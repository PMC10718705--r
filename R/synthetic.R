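#' Default synthetic item pool: ~200 acupoint codes over 19 communities
#'
#' WHO-style codes (`LU1`..`LU6`, `BL1`..`BL30`, `EX-HX1`.., ...) spread over
#' the 14 meridians and 5 extra-point regions, with per-community counts
#' roughly proportional to the real meridians' acupoint counts and scaled so
#' the pool totals 198 items — the scale of a real acupoint-disease network
#' (~197 nodes).
#'
#' @return A tibble with columns `item`, `community`.
#' @export
default_item_pool <- function() {
  counts <- c(
    "LU" = 6, "LI" = 12, "ST" = 22, "SP" = 11, "HT" = 5, "SI" = 9,
    "BL" = 30, "KI" = 13, "PC" = 5, "TE" = 11, "GB" = 20, "LR" = 7,
    "GV" = 13, "CV" = 12,
    "EX-HX" = 8, "EX-CA" = 2, "EX-B" = 5, "EX-UE" = 4, "EX-LE" = 3
  )
  items <- unlist(lapply(names(counts),
                         function(p) paste0(p, seq_len(counts[[p]]))),
                  use.names = FALSE)
  out <- assign_communities(items)
  tibble::tibble(item = out$node, community = out$community)
}

#' Configuration for the synthetic prescription generator
#'
#' Encodes the study conditions the generator emulates: ~150 case records
#' (one per treated condition) over a ~200-item pool grouped into 19
#' communities; itemsets drawn mostly within
#' a "home" community (prescriptions are meridian-concentrated) with a small
#' cross-community mixing probability; a few designated hub items organized
#' into famous combinations that dominate their own community's
#' prescriptions and are pulled in together ([hub_combos()]).
#'
#' @param n_cases Number of case records, one per condition (default 150:
#'   roughly 50 classical conditions plus ~100 literature-derived ones;
#'   this reproduces the reference network scale of ~197 nodes, ~2000
#'   edges, average weighted degree ~40 and clustering ~0.75).
#' @param pool Item pool tibble (`item`, `community`); default
#'   [default_item_pool()].
#' @param size_min,size_max Itemset size range, sampled uniformly (default
#'   3 to 12).
#' @param hub_fraction Fraction of pool items designated hubs (default 0.05,
#'   i.e. 9 hubs in 3 combos for the default pool).
#' @param hub_boost Multiplicative sampling weight of hub items in
#'   home-community and combo-partner draws (default 25: a famous
#'   combination appears in nearly every prescription of its own system).
#' @param p_cross Probability that an item draw leaves the home community
#'   (default 0.05).
#' @param seed Integer RNG seed; all generator output is a pure function of
#'   the config including the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 150, pool = default_item_pool(),
                             size_min = 3, size_max = 12,
                             hub_fraction = 0.05, hub_boost = 25,
                             p_cross = 0.05, seed = 1) {
  stopifnot(n_cases >= 1, size_min >= 1, size_min <= size_max,
            hub_fraction >= 0, hub_fraction <= 1, hub_boost > 0,
            p_cross >= 0, p_cross <= 1,
            is.data.frame(pool), all(c("item", "community") %in% names(pool)))
  pool <- tibble::as_tibble(pool)
  pool$item <- normalize_codes(pool$item)
  if (anyDuplicated(pool$item)) stop("pool items must be unique", call. = FALSE)
  if (nrow(pool) < size_max) {
    stop("item pool (", nrow(pool), ") smaller than max itemset size (",
         size_max, ")", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases), pool = pool,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 hub_fraction = hub_fraction, hub_boost = hub_boost,
                 p_cross = p_cross, seed = as.integer(seed)),
            class = "generator_config")
}

#' Designated hub items of a configuration
#'
#' `floor(hub_fraction * pool size)` items (at least one when the fraction is
#' positive) are designated hubs. Hubs are planted as small within-community
#' groups (up to 3 per community, sampled from communities large enough to
#' also hold non-hub mates), emulating famous acupoint combinations that
#' recur together across prescriptions — the structure that makes them
#' high-synergy rather than merely high-degree. The set is fixed by the
#' config seed so generation and downstream recovery checks agree on it.
#'
#' @param config A `generator_config`.
#' @return Character vector of hub item codes (possibly empty).
#' @export
planted_hubs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_hubs <- floor(config$hub_fraction * nrow(config$pool))
  if (config$hub_fraction > 0) n_hubs <- max(1L, n_hubs)
  if (n_hubs == 0) return(character())
  unname(sort(unlist(hub_combos(config))))
}

#' Planted hub combinations
#'
#' The hubs of a configuration organized into their recurring combinations
#' (groups of up to 3 items from one community each).
#'
#' @param config A `generator_config`.
#' @return A list of character vectors (possibly empty).
#' @export
hub_combos <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_hubs <- floor(config$hub_fraction * nrow(config$pool))
  if (config$hub_fraction > 0) n_hubs <- max(1L, n_hubs)
  if (n_hubs == 0) return(list())
  pool <- config$pool
  with_seed(config$seed, {
    sizes <- table(pool$community)
    eligible <- names(sizes)[sizes >= 6]
    if (length(eligible) == 0) eligible <- names(sizes)
    n_groups <- ceiling(n_hubs / 3)
    comms <- sample(eligible, min(n_groups, length(eligible)),
                    prob = as.numeric(sizes[eligible]))
    combos <- list()
    left <- n_hubs
    for (cm in comms) {
      take <- min(3L, left)
      combos <- c(combos, list(sort(sample(pool$item[pool$community == cm],
                                           take))))
      left <- left - take
    }
    if (left > 0) {
      # few eligible communities: top up with one extra combo from the rest
      extra <- sample(setdiff(pool$item, unlist(combos)), left)
      combos <- c(combos, list(sort(extra)))
    }
    combos
  })
}

#' Generate synthetic prescription-style records
#'
#' For each case a home community is sampled (probability proportional to
#' community size) and an itemset of uniform random size is drawn item by
#' item: with probability `1 - p_cross` from the home community, otherwise
#' uniformly from the whole pool. Hub items are oversampled by `hub_boost`
#' in home-community draws, and hubs come in recurring combinations
#' ([hub_combos()]): once a hub is drawn into a case, its combination
#' partners join the candidate set with boosted weight, so famous groups
#' tend to be prescribed together — the high-co-occurrence, high-synergy
#' structure planted for recovery checks.
#' Draws are without replacement within a case; when the home community is
#' exhausted the draw falls back to the whole pool.
#'
#' @param config A `generator_config`.
#' @return A records tibble (`case_id`, `item`), case ids `case0001`, ...;
#'   byte-identical across calls with the same config.
#' @examples
#' recs <- generate_records(generator_config(n_cases = 20, seed = 7))
#' build_adn(recs)
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pool <- config$pool
  combos <- hub_combos(config)
  hubs <- unlist(combos)
  base_w <- ifelse(pool$item %in% hubs, config$hub_boost, 1)
  partner_idx <- lapply(seq_len(nrow(pool)), function(i) integer(0))
  for (cb in combos) {
    idx <- match(cb, pool$item)
    for (q in seq_along(idx)) partner_idx[[idx[q]]] <- idx[-q]
  }
  comm_split <- split(seq_len(nrow(pool)), pool$community)
  comm_sizes <- lengths(comm_split)
  with_seed(config$seed + 1L, {
    # hub designation above consumes the raw seed; offset decorrelates draws
    size_range <- seq(config$size_min, config$size_max)
    sizes <- size_range[sample.int(length(size_range), config$n_cases,
                                   replace = TRUE)]
    homes <- sample(names(comm_split), config$n_cases, replace = TRUE,
                    prob = comm_sizes)
    items_per_case <- lapply(seq_len(config$n_cases), function(cs) {
      home_idx <- comm_split[[homes[cs]]]
      taken <- integer(0)
      pulled <- integer(0)
      for (d in seq_len(sizes[cs])) {
        cross <- stats::runif(1) < config$p_cross
        cand <- if (cross) seq_len(nrow(pool)) else union(home_idx, pulled)
        cand <- setdiff(cand, taken)
        if (length(cand) == 0) cand <- setdiff(seq_len(nrow(pool)), taken)
        # the hub boost acts on home/partner draws: combos are famous within
        # their own system; cross-community picks are uniform
        w <- if (cross) rep(1, length(cand)) else base_w[cand]
        pick <- if (length(cand) == 1) cand else {
          cand[sample.int(length(cand), 1, prob = w)]
        }
        taken <- c(taken, pick)
        pulled <- union(pulled, partner_idx[[pick]])
      }
      pool$item[taken]
    })
    tibble::tibble(
      case_id = rep(sprintf("case%04d", seq_len(config$n_cases)),
                    lengths(items_per_case)),
      item = unlist(items_per_case, use.names = FALSE)
    )
  })
}

#' Small named fixture networks with documented properties
#'
#' A canned set used across the test suites and examples:
#' \describe{
#'   \item{k3}{triangle, unit weights: 3 nodes, 3 edges, 1 triangle, EI 0.}
#'   \item{k4}{complete graph on 4 nodes, unit weights: 4 triangles, EI 0.}
#'   \item{path3}{path A-B-C: no triangles; removing B disconnects the rest.}
#'   \item{star3}{star with center C and two unit leaves: EI ~0.9183 bits.}
#'   \item{triangle_pendants}{5 nodes: one weighted triangle A-B-D with
#'     pendant leaves C (on B) and E (on D).}
#'   \item{planted30}{30-node ring of unit edges plus one heavy planted
#'     triangle (N01, N11, N21): the only triangle in the graph, so its
#'     members take the top-3 motif-based PageRank scores.}
#' }
#'
#' @return A named list of `adn` objects.
#' @export
fixture_networks <- function() {
  ring <- tibble::tibble(
    from = sprintf("N%02d", 1:30),
    to = sprintf("N%02d", c(2:30, 1)),
    weight = 1
  )
  planted <- dplyr::bind_rows(
    ring,
    tibble::tibble(from = c("N01", "N01", "N11"),
                   to = c("N11", "N21", "N21"),
                   weight = 5)
  )
  list(
    k3 = as_adn(tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"),
                               weight = 1)),
    k4 = as_adn(tibble::tibble(from = c("A", "A", "A", "B", "B", "C"),
                               to = c("B", "C", "D", "C", "D", "D"),
                               weight = 1)),
    path3 = as_adn(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                  weight = 1)),
    star3 = as_adn(tibble::tibble(from = c("C", "C"), to = c("L1", "L2"),
                                  weight = 1)),
    triangle_pendants = as_adn(tibble::tibble(
      from = c("A", "A", "B", "B", "D"),
      to = c("B", "D", "D", "C", "E"),
      weight = c(3, 2, 2, 1, 1)
    )),
    planted30 = as_adn(planted)
  )
}
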