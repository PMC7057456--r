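#' Discover perturbed routes from a start gene
#'
#' Depth-first search over the pathway graph, scoring each candidate route
#' incrementally against one sample and emitting the routes whose terminal
#' condition holds: for direction `"activated"` the last observed gene must
#' match the expected state propagated from a `+1` root, for
#' `"suppressed"` it must be the opposite, and in both cases the route score
#' must reach `score_cutoff`. The default cutoff of 1 recovers the strict
#' rule that only fully consistent routes are emitted; lowering it tolerates
#' a limited number of inconsistent edges.
#'
#' Extending a route can never raise its score, so the search prunes a
#' branch once the running score falls below
#' `score_cutoff * epsilon/(1 - epsilon)` — exact with respect to a full
#' enumeration while bounding work. Every qualifying sub-segment is emitted
#' independently (a long route and its prefixes are separate results). The
#' emitted set is a function of the graph and observation only, independent
#' of edge order or traversal scheduling.
#'
#' Routes on which fewer than two genes are observed are skipped; the count
#' of skipped candidates is attached as attribute `n_skipped`.
#'
#' @param graph a [pathway_graph()].
#' @param start gene id present in the graph.
#' @param obs a [sample_observation()].
#' @param hp a [hyperparams()] object.
#' @param direction `"activated"` or `"suppressed"`.
#' @param score_cutoff minimum route score in `(0, 1]`; default 1.
#' @param max_len maximum route length in genes; default 12.
#' @return List of [score_route()] results for the emitted routes, in
#'   lexicographic gene order, with attribute `n_skipped`.
#' @export
get_routes <- function(graph, start, obs, hp = hyperparams(),
                       direction = c("activated", "suppressed"),
                       score_cutoff = 1, max_len = 12L) {
  direction <- match.arg(direction)
  stopifnot(inherits(graph, "pathway_graph"),
            inherits(obs, "sample_observation"),
            score_cutoff > 0, score_cutoff <= 1)
  start <- toupper(start)
  if (!start %in% graph$nodes) {
    stop(sprintf("start gene '%s' is not in pathway '%s'", start,
                 graph$name), call. = FALSE)
  }
  tol <- 1e-9
  prune_below <- score_cutoff * hp$epsilon / (1 - hp$epsilon) - tol
  adj <- graph_adjacency(graph)
  acc <- new.env(parent = emptyenv())
  acc$hits <- list()
  acc$n_skipped <- 0L

  consider <- function(rt) {
    res <- tryCatch(score_route(rt, obs, hp),
                    routescore_undefined_score = function(e) NULL)
    if (is.null(res)) {
      acc$n_skipped <- acc$n_skipped + 1L
      return(Inf)  # unscorable yet; keep extending, never prune on it
    }
    ok <- res$score >= score_cutoff - tol &&
      res$direction == direction
    if (ok) acc$hits[[length(acc$hits) + 1L]] <- res
    res$score
  }

  walk <- function(genes, signs, on_path) {
    if (length(genes) >= max_len) return(invisible())
    nxt <- adj[[genes[length(genes)]]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_along(nxt$target)) {
      tgt <- nxt$target[i]
      if (on_path[tgt]) next
      g2 <- c(genes, tgt)
      s2 <- c(signs, nxt$sign[i])
      sc <- consider(route(g2, s2))
      if (sc < prune_below) next
      on_path[tgt] <- TRUE
      walk(g2, s2, on_path)
      on_path[tgt] <- FALSE
    }
    invisible()
  }

  on_path <- stats::setNames(logical(length(graph$nodes)), graph$nodes)
  on_path[start] <- TRUE
  walk(start, integer(), on_path)
  structure(acc$hits, n_skipped = acc$n_skipped)
}

#' Isolate activated and suppressed sub-networks of a pathway
#'
#' Runs [get_routes()] from every gene of the pathway for both directions
#' and aggregates the emitted routes into two perturbed sub-networks, whose
#' node and edge sets are exactly the unions over their member routes.
#' Per-start searches are independent, so the result does not depend on the
#' order in which start genes are processed.
#'
#' @inheritParams get_routes
#' @return A list with elements `activated` and `suppressed`, each an object
#'   of class `perturbed_subnetwork`: list with `direction`, `routes`
#'   (list of [score_route()] results), `node_set`, `edge_set` (data frame
#'   `source`, `target`, `sign`) and `sample_id`.
#' @export
find_perturbed_subnetworks <- function(graph, obs, hp = hyperparams(),
                                       score_cutoff = 1, max_len = 12L) {
  out <- lapply(c("activated", "suppressed"), function(dir) {
    hits <- lapply(graph$nodes, function(v) {
      get_routes(graph, v, obs, hp, direction = dir,
                 score_cutoff = score_cutoff, max_len = max_len)
    })
    hits <- do.call(c, lapply(hits, unclass))
    build_subnetwork(dir, hits, obs$sample_id)
  })
  stats::setNames(out, c("activated", "suppressed"))
}

build_subnetwork <- function(direction, results, sample_id) {
  nodes <- character()
  edges <- data.frame(source = character(), target = character(),
                      sign = integer(), stringsAsFactors = FALSE)
  for (res in results) {
    rt <- res$route
    w <- length(rt$genes)
    nodes <- c(nodes, rt$genes)
    edges <- rbind(edges,
                   data.frame(source = rt$genes[-w], target = rt$genes[-1L],
                              sign = rt$signs, stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(direction = direction, routes = results,
                 node_set = sort(unique(nodes)), edge_set = edges,
                 sample_id = sample_id),
            class = "perturbed_subnetwork")
}

#' @export
print.perturbed_subnetwork <- function(x, ...) {
  cat(sprintf("<perturbed_subnetwork> %s (sample %s): %d route(s), %d gene(s), %d edge(s)\n",
              x$direction, x$sample_id, length(x$routes),
              length(x$node_set), nrow(x$edge_set)))
  invisible(x)
}

#' Tabulate route results
#'
#' Flattens a list of [score_route()] results into a data frame suitable for
#' TSV export.
#'
#' @param results list of `route_result` objects.
#' @return Data frame with columns `route_id`, `length`, `score`,
#'   `s_score`, `direction`.
#' @export
route_results_table <- function(results) {
  data.frame(
    route_id = vapply(results, function(x) route_id(x$route), character(1)),
    length = vapply(results, function(x) length(x$route$genes), integer(1)),
    score = vapply(results, `[[`, numeric(1), "score"),
    s_score = vapply(results, `[[`, numeric(1), "s_score"),
    direction = vapply(results, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
}
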