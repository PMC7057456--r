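#' Construct a signed pathway graph
#'
#' A `pathway_graph` is a directed gene-regulation network: nodes are genes
#' and each edge carries a regulation sign, `+1` for activation and `-1` for
#' inhibition. Cycles are allowed (routes through the graph are always simple
#' paths, so enumeration stays finite); self-loops and parallel edges are
#' not.
#'
#' Gene identifiers are normalized to upper case so that pathway files and
#' observation tables match by exact string comparison.
#'
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (`sign` in `{+1, -1}`).
#' @param name pathway name.
#' @param nodes optional character vector of gene ids; the union of edge
#'   endpoints is always included, extra entries become isolated nodes.
#' @param display optional named character vector of human-readable labels,
#'   keyed by gene id.
#' @return An object of class `pathway_graph` with fields `name`, `nodes`,
#'   `edges` and `display`.
#' @examples
#' g <- pathway_graph(data.frame(source = "A", target = "B", sign = 1))
#' g$nodes
#' @export
pathway_graph <- function(edges, name = "pathway", nodes = NULL,
                          display = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  req <- c("source", "target", "sign")
  if (!all(req %in% names(edges))) {
    stop("edge table must have columns source, target, sign", call. = FALSE)
  }
  edges <- data.frame(source = toupper(as.character(edges$source)),
                      target = toupper(as.character(edges$target)),
                      sign = as.integer(edges$sign),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("gene ids must be non-empty strings", call. = FALSE)
  }
  if (any(!edges$sign %in% c(1L, -1L))) {
    stop("edge sign must be +1 (activation) or -1 (inhibition)",
         call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    bad <- edges$source[edges$source == edges$target][1L]
    stop(sprintf("self-loop on gene '%s' is not allowed", bad),
         call. = FALSE)
  }
  # identical duplicate rows collapse; same pair with opposite signs is a
  # contradiction in the curated topology and must be resolved upstream
  edges <- unique(edges)
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1L]
    pair <- strsplit(bad, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("conflicting duplicate edge %s -> %s (both signs present)",
                 pair[1L], pair[2L]), call. = FALSE)
  }
  all_nodes <- sort(unique(c(edges$source, edges$target,
                             toupper(as.character(nodes)))))
  ord <- order(edges$source, edges$target)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, nodes = all_nodes, edges = edges,
                 display = display),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d genes, %d signed edges (%d activation, %d inhibition)\n",
              x$name, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Read a signed edge-list TSV
#'
#' The file must be tab-separated with header columns `source`, `target`
#' and `sign`; sign tokens are `activation`/`inhibition` or `+1`/`-1`.
#' Row order does not affect the resulting graph.
#'
#' @param path file path.
#' @param name pathway name (defaults to the file base name).
#' @return A [pathway_graph()].
#' @export
load_edge_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  req <- c("source", "target", "sign")
  if (!all(req %in% names(tab))) {
    stop(sprintf("%s: expected header columns source, target, sign", path),
         call. = FALSE)
  }
  sign <- parse_sign_tokens(tab$sign, path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pathway_graph(data.frame(source = tab$source, target = tab$target,
                           sign = sign, stringsAsFactors = FALSE),
                name = name)
}

parse_sign_tokens <- function(tokens, path) {
  map <- c("activation" = 1L, "inhibition" = -1L,
           "+1" = 1L, "1" = 1L, "-1" = -1L)
  out <- map[tolower(trimws(tokens))]
  if (anyNA(out)) {
    line <- which(is.na(out))[1L]
    stop(sprintf("%s: unknown sign token '%s' at data line %d",
                 path, tokens[line], line), call. = FALSE)
  }
  unname(out)
}

#' Write a pathway graph as a signed edge-list TSV
#'
#' Inverse of [load_edge_list()]; signs are written as the tokens
#' `activation` and `inhibition`.
#'
#' @param graph a [pathway_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  tab <- data.frame(source = graph$edges$source,
                    target = graph$edges$target,
                    sign = ifelse(graph$edges$sign == 1L,
                                  "activation", "inhibition"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a pathway graph to an igraph object
#'
#' The regulation sign is stored in the `sign` edge attribute. Used by the
#' GraphML/DOT exporters and handy for interactive inspection.
#'
#' @param graph a [pathway_graph()].
#' @return An [igraph::igraph] directed graph.
#' @export
pathway_igraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  g <- igraph::graph_from_data_frame(graph$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = graph$nodes)
  igraph::E(g)$sign <- graph$edges$sign
  g
}

#' Write a pathway graph to GraphML
#'
#' The sign is stored as an integer edge attribute `sign`; extra per-node or
#' per-edge attributes (e.g. activation/suppression flags) may be supplied
#' as named vectors/data frames aligned with `graph$nodes` and
#' `graph$edges`.
#'
#' @param graph a [pathway_graph()].
#' @param path output file path.
#' @param node_attrs optional data frame of node attributes, one row per
#'   node in `graph$nodes` order.
#' @param edge_attrs optional data frame of edge attributes, one row per
#'   edge in `graph$edges` order.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, node_attrs = NULL, edge_attrs = NULL,
                          format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- pathway_igraph(graph)
  if (!is.null(node_attrs)) {
    for (nm in names(node_attrs)) {
      g <- igraph::set_vertex_attr(g, nm, value = node_attrs[[nm]])
    }
  }
  if (!is.null(edge_attrs)) {
    for (nm in names(edge_attrs)) {
      g <- igraph::set_edge_attr(g, nm, value = edge_attrs[[nm]])
    }
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Load a pathway graph back from GraphML
#'
#' Round-trip companion of [write_graphml()].
#'
#' @param path GraphML file written by [write_graphml()].
#' @param name pathway name.
#' @return A [pathway_graph()].
#' @export
load_graphml <- function(path, name = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pathway_graph(data.frame(source = ed$from, target = ed$to,
                           sign = as.integer(ed$sign),
                           stringsAsFactors = FALSE),
                name = name, nodes = igraph::V(g)$name)
}
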