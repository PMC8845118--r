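# Compound-target (bipartite) and compound-target-disease (tripartite)
# networks. Edges are deduplicated sets; node namespaces are kept separate
# internally with C:/T:/D: prefixes (stripped on export) so a compound id
# can never collide with a target id.

#' Build a compound-target bipartite network from a prediction table
#'
#' @param predictions data.frame with `compound_id` and `target_id`;
#'   duplicate pairs are collapsed.
#' @return An object of class `ct_network`: list with `compound_nodes`,
#'   `target_nodes` and a deduplicated `edges` data.frame.
#' @export
build_ct_network <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    return(structure(list(compound_nodes = character(),
                          target_nodes = character(),
                          edges = data.frame(compound_id = character(),
                                             target_id = character(),
                                             stringsAsFactors = FALSE)),
                     class = "ct_network"))
  }
  edges <- unique(predictions[, c("compound_id", "target_id")])
  edges <- edges[order(edges$compound_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    compound_nodes = sort(unique(edges$compound_id)),
    target_nodes = sort(unique(edges$target_id)),
    edges = edges
  ), class = "ct_network")
}

#' Number of nodes and edges of a compound-target network
#'
#' @param net A `ct_network` or `ctd_network`.
#' @return Named integer vector `n_compounds`, `n_targets`, (`n_categories`,)
#'   `n_nodes`, `n_edges`.
#' @export
network_summary <- function(net) {
  if (inherits(net, "ctd_network")) {
    c(n_compounds = length(net$ct$compound_nodes),
      n_targets = length(net$ct$target_nodes),
      n_categories = length(net$category_nodes),
      n_nodes = length(net$ct$compound_nodes) + length(net$ct$target_nodes) +
        length(net$category_nodes),
      n_edges = nrow(net$ct$edges) + nrow(net$tc_edges))
  } else {
    c(n_compounds = length(net$compound_nodes),
      n_targets = length(net$target_nodes),
      n_nodes = length(net$compound_nodes) + length(net$target_nodes),
      n_edges = nrow(net$edges))
  }
}

#' Degree table for one part of a bipartite network
#'
#' @param net A `ct_network`.
#' @param part `"compound"` or `"target"`.
#' @return data.frame (`id`, `degree`, `part`) sorted by descending degree,
#'   ties broken by id.
#' @export
degree_table <- function(net, part = c("compound", "target")) {
  part <- match.arg(part)
  nodes <- if (part == "compound") net$compound_nodes else net$target_nodes
  col <- if (part == "compound") "compound_id" else "target_id"
  deg <- table(factor(net$edges[[col]], levels = nodes))
  res <- data.frame(id = names(deg), degree = as.integer(deg),
                    part = part, stringsAsFactors = FALSE)
  res <- res[order(-res$degree, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select core constituents by degree threshold
#'
#' Keeps every entry whose degree reaches the threshold (inclusive),
#' ranked by descending degree with ties broken by id. With the default
#' threshold of 17 this reproduces the study's core-constituent selection.
#'
#' @param table A [degree_table()] result (or any data.frame with `id` and
#'   `degree`).
#' @param threshold Inclusive minimum degree, default 17.
#' @return The surviving rows, ranked.
#' @export
filter_core_constituents <- function(table, threshold = 17L) {
  stopifnot(threshold >= 0)
  res <- table[table$degree >= threshold, , drop = FALSE]
  res <- res[order(-res$degree, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extend a compound-target network with disease/pathology categories
#'
#' Adds one target-category edge per mapped target. By default each target
#' maps to exactly one category; set `multi = TRUE` to allow multiple
#' category rows per target.
#'
#' @param net A `ct_network`.
#' @param category_map data.frame (`target_id`, `category`); every target
#'   must exist in `net`.
#' @param multi Allow multiple categories per target (default `FALSE`).
#' @return An object of class `ctd_network`: list with `ct` (the input
#'   network), `category_nodes` and `tc_edges`.
#' @export
build_ctd_network <- function(net, category_map, multi = FALSE) {
  stopifnot(inherits(net, "ct_network"))
  if (is.null(category_map) || nrow(category_map) == 0L) {
    tc <- data.frame(target_id = character(), category = character(),
                     stringsAsFactors = FALSE)
    return(structure(list(ct = net, category_nodes = character(), tc_edges = tc),
                     class = "ctd_network"))
  }
  unknown <- setdiff(category_map$target_id, net$target_nodes)
  if (length(unknown) > 0L) {
    stop("category map references unknown targets: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  tc <- unique(category_map[, c("target_id", "category")])
  if (!multi && anyDuplicated(tc$target_id)) {
    stop("multiple categories for one target; set multi = TRUE to allow",
         call. = FALSE)
  }
  tc <- tc[order(tc$target_id, tc$category), , drop = FALSE]
  rownames(tc) <- NULL
  structure(list(ct = net, category_nodes = sort(unique(tc$category)),
                 tc_edges = tc), class = "ctd_network")
}

#' Per-category target counts of a tripartite network
#'
#' @param tri A `ctd_network`.
#' @return data.frame (`category`, `n_targets`) summing to the number of
#'   mapped targets; categories with no targets are kept at zero.
#' @export
category_counts <- function(tri) {
  stopifnot(inherits(tri, "ctd_network"))
  if (length(tri$category_nodes) == 0L) {
    return(data.frame(category = character(), n_targets = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(factor(tri$tc_edges$category, levels = tri$category_nodes))
  res <- data.frame(category = names(counts), n_targets = as.integer(counts),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_targets, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Typed edge list (source, interaction, target) with raw (unprefixed) ids,
# shared by all exporters.
network_edge_list <- function(net) {
  if (inherits(net, "ct_network")) {
    data.frame(source = net$edges$compound_id, interaction = "ct",
               target = net$edges$target_id, stringsAsFactors = FALSE)
  } else if (inherits(net, "ctd_network")) {
    rbind(network_edge_list(net$ct),
          data.frame(source = net$tc_edges$target_id, interaction = "tc",
                     target = net$tc_edges$category, stringsAsFactors = FALSE))
  } else if (inherits(net, "igraph")) {
    e <- igraph::as_edgelist(net)
    data.frame(source = e[, 1L], interaction = "pp", target = e[, 2L],
               stringsAsFactors = FALSE)
  } else {
    stop("unsupported network object", call. = FALSE)
  }
}

#' Export a network for external visualization tools
#'
#' Writes a `ct_network`, `ctd_network` or igraph PPI graph in SIF,
#' GraphML or edge-list TSV format. Node and edge counts survive a
#' round-trip through [import_network()].
#'
#' @param net The network object.
#' @param path Output file path.
#' @param format `"SIF"`, `"GraphML"` or `"TSV"` (case-insensitive).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("SIF", "GraphML", "TSV")) {
  format <- toupper(format[1L])
  if (!format %in% c("SIF", "GRAPHML", "TSV")) {
    stop("unknown export format: ", format, call. = FALSE)
  }
  el <- network_edge_list(net)
  if (format == "SIF") {
    writeLines(paste(el$source, el$interaction, el$target, sep = "\t"), path)
  } else if (format == "TSV") {
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    # internal prefixing keeps part namespaces distinct inside the graph file
    pre <- prefix_edge_list(net, el)
    g <- igraph::graph_from_data_frame(pre[, c("source", "target")],
                                       directed = FALSE)
    igraph::E(g)$interaction <- pre$interaction
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

prefix_edge_list <- function(net, el) {
  if (inherits(net, "igraph")) return(el)
  src_pref <- ifelse(el$interaction == "ct", "C:", "T:")
  tgt_pref <- ifelse(el$interaction == "ct", "T:", "D:")
  data.frame(source = paste0(src_pref, el$source),
             interaction = el$interaction,
             target = paste0(tgt_pref, el$target), stringsAsFactors = FALSE)
}

#' Re-import an exported network edge list
#'
#' Reads SIF, GraphML or TSV written by [export_network()] back into a
#' plain (source, interaction, target) edge data.frame with part prefixes
#' stripped, for round-trip checks and downstream processing.
#'
#' @param path File path.
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return data.frame (`source`, `interaction`, `target`).
#' @export
import_network <- function(path, format = c("SIF", "GraphML", "TSV")) {
  format <- toupper(format[1L])
  if (format == "SIF") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    el <- data.frame(source = vapply(parts, `[`, "", 1L),
                     interaction = vapply(parts, `[`, "", 2L),
                     target = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
  } else if (format == "TSV") {
    el <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else if (format == "GRAPHML") {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_edgelist(g)
    # canonical orientation for part-prefixed nodes (C before T before D);
    # igraph does not preserve endpoint order for undirected edges
    rank <- function(x) match(substr(x, 1L, 2L), c("C:", "T:", "D:"), nomatch = 0L)
    swap <- rank(e[, 1L]) > rank(e[, 2L])
    e[swap, ] <- e[swap, c(2L, 1L)]
    el <- data.frame(source = sub("^[CTD]:", "", e[, 1L]),
                     interaction = igraph::E(g)$interaction,
                     target = sub("^[CTD]:", "", e[, 2L]), stringsAsFactors = FALSE)
  } else {
    stop("unknown import format: ", format, call. = FALSE)
  }
  el
}
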