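#' Construct a pathway route
#'
#' A route is a simple directed path through a pathway graph: an ordered
#' sequence of at least two distinct genes together with the regulation sign
#' of each traversed edge.
#'
#' @param genes character vector of gene ids, pairwise distinct, length >= 2.
#' @param signs integer vector of edge signs in `{+1, -1}`, length
#'   `length(genes) - 1`.
#' @return An object of class `route` with fields `genes` and `signs`.
#' @examples
#' route(c("A", "B", "C"), c(1, -1))
#' @export
route <- function(genes, signs) {
  genes <- toupper(as.character(genes))
  signs <- as.integer(signs)
  if (length(genes) < 2L) stop("a route needs at least two genes",
                               call. = FALSE)
  if (anyDuplicated(genes)) stop("route genes must be pairwise distinct",
                                 call. = FALSE)
  if (length(signs) != length(genes) - 1L) {
    stop("need one edge sign per consecutive gene pair", call. = FALSE)
  }
  if (any(!signs %in% c(1L, -1L))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  structure(list(genes = genes, signs = signs), class = "route")
}

#' @export
print.route <- function(x, ...) {
  arrows <- ifelse(x$signs == 1L, " -> ", " -| ")
  cat("<route> ",
      paste0(x$genes[-length(x$genes)], arrows, collapse = ""),
      x$genes[length(x$genes)], "\n", sep = "")
  invisible(x)
}

#' @export
length.route <- function(x) length(x$genes)

#' Route identifier string
#'
#' Stable textual id used in result tables: genes joined by `,`.
#'
#' @param r a [route()].
#' @return A single string.
#' @export
route_id <- function(r) paste(r$genes, collapse = ",")

#' Build a route from a gene sequence of a graph
#'
#' Looks up each consecutive edge in the graph and takes its sign; errors if
#' any consecutive pair is not an edge.
#'
#' @param graph a [pathway_graph()].
#' @param genes ordered character vector of gene ids.
#' @return A [route()].
#' @export
route_from_genes <- function(graph, genes) {
  genes <- toupper(as.character(genes))
  key <- paste(graph$edges$source, graph$edges$target, sep = "\r")
  sign_of <- stats::setNames(graph$edges$sign, key)
  want <- paste(genes[-length(genes)], genes[-1L], sep = "\r")
  signs <- sign_of[want]
  if (anyNA(signs)) {
    i <- which(is.na(signs))[1L]
    stop(sprintf("%s -> %s is not an edge of pathway '%s'",
                 genes[i], genes[i + 1L], graph$name), call. = FALSE)
  }
  route(genes, unname(signs))
}

#' Enumerate simple-path routes from a start gene
#'
#' Depth-first search over the pathway graph collecting every simple path
#' (no gene revisited) of length 2 to `max_len` that begins at `start`.
#' Cycles are never traversed: a branch stops as soon as it would revisit a
#' gene, which keeps enumeration finite on cyclic pathways. The result is
#' ordered lexicographically by gene sequence and does not depend on the
#' order in which edges were supplied.
#'
#' Exhaustive simple-path enumeration is exponential in dense graphs, hence
#' the `max_len` cap. Enumeration from different start genes is independent,
#' so callers may shard by start node; the sequential result is the
#' reference.
#'
#' @param graph a [pathway_graph()].
#' @param start gene id present in the graph.
#' @param max_len maximum number of genes per route (>= 2); default 12.
#' @return List of [route()] objects in lexicographic gene order.
#' @examples
#' g <- pathway_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                               sign = c(1, -1)))
#' enumerate_routes(g, "A")
#' @export
enumerate_routes <- function(graph, start, max_len = 12L) {
  stopifnot(inherits(graph, "pathway_graph"))
  start <- toupper(start)
  if (!start %in% graph$nodes) {
    stop(sprintf("start gene '%s' is not in pathway '%s'",
                 start, graph$name), call. = FALSE)
  }
  max_len <- as.integer(max_len)
  if (max_len < 2L) stop("max_len must be at least 2", call. = FALSE)
  adj <- graph_adjacency(graph)
  acc <- new.env(parent = emptyenv())
  acc$routes <- vector("list", 64L)
  acc$n <- 0L

  walk <- function(genes, signs, on_path) {
    if (length(genes) >= max_len) return(invisible())
    nxt <- adj[[genes[length(genes)]]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_along(nxt$target)) {
      tgt <- nxt$target[i]
      if (on_path[tgt]) next
      g2 <- c(genes, tgt)
      s2 <- c(signs, nxt$sign[i])
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$routes)) {
        length(acc$routes) <- 2L * length(acc$routes)
      }
      acc$routes[[acc$n]] <- route(g2, s2)
      on_path[tgt] <- TRUE
      walk(g2, s2, on_path)
      on_path[tgt] <- FALSE
    }
    invisible()
  }

  on_path <- stats::setNames(logical(length(graph$nodes)), graph$nodes)
  on_path[start] <- TRUE
  walk(start, integer(), on_path)
  acc$routes[seq_len(acc$n)]
}

# out-adjacency with targets pre-sorted, giving lexicographic DFS order
graph_adjacency <- function(graph) {
  ed <- graph$edges
  out <- split(seq_len(nrow(ed)), ed$source)
  lapply(out, function(idx) {
    idx <- idx[order(ed$target[idx])]
    list(target = ed$target[idx], sign = ed$sign[idx])
  })
}

#' Enumerate routes from every start gene
#'
#' Union of [enumerate_routes()] over all nodes of the graph. Each simple
#' path appears exactly once (a path is only found from its own first gene).
#'
#' @inheritParams enumerate_routes
#' @return List of [route()] objects.
#' @export
enumerate_all_routes <- function(graph, max_len = 12L) {
  out <- lapply(graph$nodes, function(v) enumerate_routes(graph, v, max_len))
  do.call(c, out)
}
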