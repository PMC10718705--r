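#' Default 19-community partition of acupoint codes
#'
#' Acupoints lie on 14 meridians (lung, large intestine, stomach, spleen,
#' heart, small intestine, bladder, kidney, pericardium, triple burner,
#' gallbladder, liver, governing vessel, conception vessel), plus 5
#' extra-point body regions (head, chest/abdomen, dorsum, upper limbs,
#' lower limbs). Standard code prefixes map onto these 19 communities; both
#' the `EX-HN` and `EX-HX` spellings of the head/neck extra points are
#' accepted.
#'
#' @return A tibble with columns `prefix` and `community`. The 19 distinct
#'   community labels define the default partition for
#'   [assign_communities()] and [top_k_per_community()].
#' @export
default_partition <- function() {
  tibble::tribble(
    ~prefix,  ~community,
    "LU",     "Lung meridian",
    "LI",     "Large intestine meridian",
    "ST",     "Stomach meridian",
    "SP",     "Spleen meridian",
    "HT",     "Heart meridian",
    "SI",     "Small intestine meridian",
    "BL",     "Bladder meridian",
    "KI",     "Kidney meridian",
    "PC",     "Pericardium meridian",
    "TE",     "Triple burner meridian",
    "GB",     "Gallbladder meridian",
    "LR",     "Liver meridian",
    "GV",     "Governing vessel",
    "CV",     "Conception vessel",
    "EX-HN",  "Extra points (head)",
    "EX-HX",  "Extra points (head)",
    "EX-CA",  "Extra points (chest and abdomen)",
    "EX-B",   "Extra points (dorsum)",
    "EX-UE",  "Extra points (upper limbs)",
    "EX-LE",  "Extra points (lower limbs)"
  )
}

#' Assign nodes to communities
#'
#' With a prefix partition (column `prefix`, as from [default_partition()])
#' each code is matched to the longest prefix that starts it; with an
#' explicit partition (columns `node`, `community`, e.g. a two-column TSV
#' override) codes are looked up directly. Unmatched codes are labelled
#' `"unassigned"` with a warning.
#'
#' @param nodes Character vector of node codes (normalized internally).
#' @param partition A prefix or node partition tibble. Default:
#'   [default_partition()].
#' @return A tibble with columns `node`, `community`.
#' @examples
#' assign_communities(c("LI4", "EX-UE9"))
#' @export
assign_communities <- function(nodes, partition = default_partition()) {
  nodes <- normalize_codes(nodes)
  stopifnot(is.data.frame(partition))
  if ("node" %in% names(partition)) {
    idx <- match(nodes, normalize_codes(partition$node))
    community <- partition$community[idx]
  } else if ("prefix" %in% names(partition)) {
    pref <- partition[order(-nchar(partition$prefix)), ]
    community <- rep(NA_character_, length(nodes))
    for (r in seq_len(nrow(pref))) {
      hit <- is.na(community) & startsWith(nodes, pref$prefix[r])
      community[hit] <- pref$community[r]
    }
  } else {
    stop("partition must have a `prefix` or a `node` column", call. = FALSE)
  }
  if (anyNA(community)) {
    warning("unassigned node code(s): ",
            paste(unique(nodes[is.na(community)]), collapse = ", "),
            call. = FALSE)
    community[is.na(community)] <- "unassigned"
  }
  tibble::tibble(node = nodes, community = community)
}

#' Select the top-k key nodes of each community
#'
#' Within each community, nodes are ranked by score (descending, ties broken
#' lexicographically by code) and the top `k` retained; communities with
#' fewer than `k` members return all of them, and empty communities are
#' omitted.
#'
#' @param scores A tibble with columns `node`, `score` (e.g. a
#'   `pagerank_scores` object or any centrality table).
#' @param partition Partition accepted by [assign_communities()].
#' @param k Number of key nodes per community (default 3).
#' @return A `key_node_report` tibble with columns `community`, `rank`,
#'   `node`, `score`.
#' @export
top_k_per_community <- function(scores, partition = default_partition(),
                                k = 3) {
  stopifnot(is.data.frame(scores), all(c("node", "score") %in% names(scores)),
            k >= 1)
  comm <- assign_communities(scores$node, partition)
  out <- dplyr::inner_join(tibble::as_tibble(scores)[, c("node", "score")],
                           comm, by = "node")
  out <- dplyr::arrange(out, .data$community, dplyr::desc(.data$score),
                        .data$node)
  out <- dplyr::slice_head(dplyr::group_by(out, .data$community), n = k)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  out <- dplyr::ungroup(out)
  structure(out[, c("community", "rank", "node", "score")],
            class = c("key_node_report", class(tibble::tibble())))
}

#' Format a key-node report as one row per community
#'
#' Collapses a [top_k_per_community()] report into the compact
#' `community | node1, node2, node3` layout, optionally written as TSV or
#' Markdown.
#'
#' @param report A `key_node_report`.
#' @param path Optional output file path.
#' @param format `"tsv"` or `"markdown"` (used when `path` is given).
#' @return A tibble with columns `community`, `key_nodes`.
#' @export
format_key_node_report <- function(report, path = NULL,
                                   format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(report),
            all(c("community", "rank", "node") %in% names(report)))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(tibble::as_tibble(report), .data$rank),
                    .data$community),
    key_nodes = paste(.data$node, collapse = ", "),
    .groups = "drop"
  )
  if (!is.null(path)) {
    if (format == "tsv") {
      utils::write.table(as.data.frame(out), path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    } else {
      lines <- c("| Community | Key nodes |", "| --- | --- |",
                 sprintf("| %s | %s |", out$community, out$key_nodes))
      writeLines(lines, path)
    }
  }
  out
}
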