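#' Normalize item codes
#'
#' Trims whitespace and upper-cases acupoint-style item codes so that
#' `"st36 "` and `"ST36"` refer to the same node.
#'
#' @param x Character vector of item codes.
#' @return Character vector of normalized codes.
#' @export
normalize_codes <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Coerce prescription-style records to a validated long tibble
#'
#' Records map one case (e.g. a disease) to the set of item codes (e.g.
#' acupoints) used together for it. Accepted inputs are a long data frame
#' with columns `case_id` and `item`, or a named list of character vectors
#' (`case_id -> items`). Codes are whitespace-trimmed and upper-cased and
#' duplicate (case, item) memberships are collapsed, so each row is one set
#' membership.
#'
#' @param records Data frame with columns `case_id`, `item`, or a named list
#'   of character vectors.
#' @return A tibble with columns `case_id` (character) and `item` (character),
#'   one row per distinct set membership.
#' @export
as_records <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records)))) {
      stop("named list records require a non-empty name for every case",
           call. = FALSE)
    }
    records <- tibble::tibble(
      case_id = rep(names(records), lengths(records)),
      item = unlist(records, use.names = FALSE)
    )
  }
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame or a named list of item vectors",
         call. = FALSE)
  }
  if (!all(c("case_id", "item") %in% names(records))) {
    stop("`records` must have columns `case_id` and `item`", call. = FALSE)
  }
  out <- tibble::as_tibble(records[, c("case_id", "item")])
  out$case_id <- trimws(as.character(out$case_id))
  out$item <- normalize_codes(out$item)
  bad <- unique(out$case_id[!nzchar(out$item)])
  if (length(bad) > 0) {
    stop("record(s) with empty item code: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(out$case_id))) {
    stop("records with empty case_id are not allowed", call. = FALSE)
  }
  dplyr::distinct(out)
}

new_adn <- function(edges, nodes) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  nodes <- sort(unique(as.character(nodes)))
  if (nrow(edges) > 0) {
    # canonical order: from < to lexicographically, rows sorted
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- dplyr::arrange(edges, .data$from, .data$to)
    if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
    if (any(edges$weight <= 0)) stop("edge weights must be positive", call. = FALSE)
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      stop("every edge endpoint must be a known node", call. = FALSE)
    }
    if (anyDuplicated(paste(edges$from, edges$to))) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
  }
  structure(edges, nodes = nodes,
            class = c("adn", class(tibble::tibble())))
}

#' Build a weighted co-occurrence network from prescription records
#'
#' Constructs the acupoint-disease network (ADN): nodes are item codes and
#' an undirected edge joins two items whenever they appear together in at
#' least one case; the edge weight is the number of cases in which the pair
#' co-occurs. Items that never co-occur with a partner are kept as isolated
#' nodes.
#'
#' @param records Records in any form accepted by [as_records()].
#' @return An `adn` object: a tibble of edges (`from`, `to`, `weight`) with
#'   the full node set in `attr(, "nodes")`.
#' @examples
#' recs <- list(D1 = c("a", "b", "c"), D2 = c("a", "b"))
#' net <- build_adn(recs)
#' net            # (A,B):2 (A,C):1 (B,C):1
#' adn_nodes(net)
#' @export
build_adn <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0) return(new_adn(empty_edges(), character()))
  nodes <- unique(records$item)
  sets <- split(records$item, records$case_id)
  short <- names(sets)[lengths(sets) < 1]
  if (length(short) > 0) {
    stop("record(s) with no items: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  pair_list <- lapply(sets, function(items) {
    items <- sort(items)
    if (length(items) < 2) return(NULL)
    idx <- utils::combn(length(items), 2)
    tibble::tibble(from = items[idx[1, ]], to = items[idx[2, ]])
  })
  pairs <- dplyr::bind_rows(pair_list)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(new_adn(empty_edges(), nodes))
  }
  edges <- dplyr::count(pairs, .data$from, .data$to, name = "weight")
  new_adn(edges, nodes)
}

empty_edges <- function() {
  tibble::tibble(from = character(), to = character(), weight = integer())
}

#' Construct an `adn` network directly from an edge list
#'
#' @param edges Data frame with columns `from`, `to`, `weight` (undirected,
#'   one row per unordered pair).
#' @param nodes Optional character vector of node names; defaults to the
#'   endpoints present in `edges`. Extra names become isolated nodes.
#' @return An `adn` object.
#' @export
as_adn <- function(edges, nodes = NULL) {
  if (inherits(edges, "adn")) return(edges)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    edges$from <- normalize_codes(edges$from)
    edges$to <- normalize_codes(edges$to)
  }
  if (is.null(nodes)) nodes <- c(edges$from, edges$to)
  new_adn(edges, normalize_codes(nodes))
}

#' @export
print.adn <- function(x, ...) {
  cat(sprintf("# Weighted co-occurrence network: %d nodes, %d edges\n",
              length(attr(x, "nodes")), nrow(x)))
  NextMethod()
  invisible(x)
}

#' Node set of a network
#' @param net An `adn` object.
#' @return Character vector of node names (includes isolated nodes).
#' @export
adn_nodes <- function(net) {
  stopifnot(inherits(net, "adn"))
  attr(net, "nodes")
}

#' Symmetric weight matrix of a network
#'
#' @param net An `adn` object.
#' @return A dense symmetric numeric matrix with zero diagonal, rows and
#'   columns named and ordered by [adn_nodes()].
#' @export
weight_matrix <- function(net) {
  nodes <- adn_nodes(net)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net) > 0) {
    i <- match(net$from, nodes)
    j <- match(net$to, nodes)
    W[cbind(i, j)] <- net$weight
    W[cbind(j, i)] <- net$weight
  }
  W
}

#' Convert a network to an igraph graph
#'
#' @param net An `adn` object.
#' @return An undirected `igraph` graph with a `weight` edge attribute;
#'   isolated nodes are preserved.
#' @export
adn_igraph <- function(net) {
  nodes <- adn_nodes(net)
  igraph::graph_from_data_frame(
    as.data.frame(net)[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
}

#' Summary attributes of a network
#'
#' Reports node and edge counts, the average weighted degree
#' (2 x total edge weight / node count) and the mean unweighted local
#' clustering coefficient (nodes of degree < 2 contribute 0), together
#' with the degree histogram.
#'
#' @param net An `adn` object.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`,
#'   `avg_weighted_degree`, `avg_clustering`, and a list-column
#'   `degree_histogram` holding a tibble (`degree`, `count`).
#' @export
network_attributes <- function(net) {
  stopifnot(inherits(net, "adn"))
  nodes <- adn_nodes(net)
  n <- length(nodes)
  awd <- if (n > 0) 2 * sum(net$weight) / n else 0
  if (n > 0) {
    g <- adn_igraph(net)
    cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero",
                               weights = NA)
    deg <- igraph::degree(g)
    hist_tbl <- dplyr::count(tibble::tibble(degree = as.integer(deg)),
                             .data$degree, name = "count")
  } else {
    cc <- 0
    hist_tbl <- tibble::tibble(degree = integer(), count = integer())
  }
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(net),
    avg_weighted_degree = awd,
    avg_clustering = cc,
    degree_histogram = list(hist_tbl)
  )
}
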