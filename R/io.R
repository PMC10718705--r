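#' Read prescription-style records from disk
#'
#' Two formats are supported: `"json"`, a single object mapping each case id
#' to an array of item codes (`{"Insomnia": ["HT7", "SP6"], ...}`), and
#' `"csv"`, a long comma-separated table with a header row and columns
#' `case_id,item`. Codes are normalized and duplicate memberships collapsed
#' via [as_records()].
#'
#' @param path File path.
#' @param format One of `"json"`, `"csv"`. Defaults from the file extension.
#' @return A records tibble (`case_id`, `item`).
#' @export
read_records <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path, c(json = "json", csv = "csv"))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(obj) && !is.character(obj)) {
      stop("JSON records must be an object mapping case ids to code arrays",
           call. = FALSE)
    }
    return(as_records(as.list(obj)))
  }
  tab <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (!all(c("case_id", "item") %in% names(tab))) {
    stop("CSV records need header columns `case_id` and `item` (line 1 of ",
         path, ")", call. = FALSE)
  }
  bad <- which(!nzchar(trimws(tab$item)) | !nzchar(trimws(tab$case_id)))
  if (length(bad) > 0) {
    stop("malformed CSV record row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  as_records(tab)
}

#' Write prescription-style records to disk
#'
#' @param records Records in any form accepted by [as_records()].
#' @param path Output file path.
#' @param format `"json"` (case id -> array of codes) or `"csv"` (long form).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("auto", "json", "csv")) {
  records <- as_records(records)
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path, c(json = "json", csv = "csv"))
  if (format == "json") {
    obj <- split(records$item, records$case_id)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

format_from_ext <- function(path, map) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% names(map)) return(unname(map[ext]))
  stop("cannot infer format from extension ", sQuote(ext),
       "; pass `format` explicitly", call. = FALSE)
}

#' Write a network to disk
#'
#' `"edgelist"` writes a tab-separated file with a header line
#' `from<TAB>to<TAB>weight`; isolated nodes, which an edge list cannot carry,
#' are recorded on a leading `# isolated:` comment line so that a round trip
#' reproduces the network exactly (generic TSV readers skip the comment).
#' `"graphml"` writes GraphML with a numeric `weight` edge attribute
#' (Gephi-compatible) and preserves isolated nodes natively.
#'
#' @param net An `adn` object.
#' @param path Output file path.
#' @param format `"edgelist"`, `"graphml"`, or `"auto"` (from extension:
#'   `.tsv` / `.graphml`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("auto", "edgelist", "graphml")) {
  stopifnot(inherits(net, "adn"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- format_from_ext(path, c(tsv = "edgelist", graphml = "graphml"))
  }
  if (format == "graphml") {
    igraph::write_graph(adn_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  iso <- setdiff(adn_nodes(net), c(net$from, net$to))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(iso) > 0) {
    writeLines(paste0("# isolated: ", paste(iso, collapse = "\t")), con)
  }
  writeLines("from\tto\tweight", con)
  if (nrow(net) > 0) {
    writeLines(paste(net$from, net$to, net$weight, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network from disk
#'
#' Counterpart of [write_network()]; `read_network(write_network(net, p), p)`
#' reproduces nodes, edges and weights exactly.
#'
#' @param path File path.
#' @param format `"edgelist"`, `"graphml"`, or `"auto"`.
#' @return An `adn` object.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- format_from_ext(path, c(tsv = "edgelist", graphml = "graphml"))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el) > 0 && is.null(el$weight)) {
      stop("GraphML file has no `weight` edge attribute: ", path, call. = FALSE)
    }
    return(as_adn(el[, intersect(c("from", "to", "weight"), names(el))],
                  nodes = igraph::V(g)$name))
  }
  lines <- readLines(path, encoding = "UTF-8")
  iso <- character()
  iso_line <- grepl("^# isolated:", lines)
  if (any(iso_line)) {
    iso <- unlist(strsplit(sub("^# isolated:\\s*", "", lines[iso_line]), "\t"))
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0 || body[1] != "from\tto\tweight") {
    stop("edge-list TSV must start with header `from\tto\tweight`: ", path,
         call. = FALSE)
  }
  body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(as_adn(empty_edges(), nodes = iso))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    off <- sum(iso_line) + 1L  # comment + header lines precede the body
    stop("malformed edge-list line(s): ",
         paste(bad + off, collapse = ", "), " in ", path, call. = FALSE)
  }
  m <- do.call(rbind, parts)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    off <- sum(iso_line) + 1L
    stop("non-numeric weight on line(s): ",
         paste(which(is.na(w)) + off, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  edges <- tibble::tibble(from = m[, 1], to = m[, 2], weight = w)
  as_adn(edges, nodes = c(edges$from, edges$to, iso))
}
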