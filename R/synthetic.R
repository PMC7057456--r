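# evaluate expr under a temporary RNG state; restores the caller's stream so
# generators are pure functions of their seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic fixture
#'
#' Collects the knobs of the synthetic pathway/observation generators. The
#' defaults emulate a small curated signaling pathway probed by a
#' discretized two-channel expression experiment: mostly activating edges
#' (`activation_fraction = 0.7`, as in typical KEGG signaling maps), a
#' per-gene flip rate of 0.1 (matching the error rate the scoring model is
#' built to tolerate), 10% missing measurements, and no mutation evidence
#' (the common case; mutation data is sparse).
#'
#' @param n_genes number of genes (>= 2).
#' @param topology `"chain"`, `"tree"`, `"dag"` or `"cyclic"`.
#' @param activation_fraction fraction of activation edges in `[0, 1]`.
#' @param flip_rate per-gene probability of contradicting the consistent
#'   pattern, in `[0, 1]`.
#' @param missing_rate per-gene probability of a missing expression value.
#' @param mutation_mode `"none"`, `"match_expression"` (mutation evidence
#'   equals the generated expression, making the reduced-score closed form
#'   exact) or `"random"`.
#' @param n_samples number of samples generated by [make_observation_set()].
#' @param seed integer seed; fully determines all generator output.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 8L, topology = c("chain", "tree", "dag",
                                                    "cyclic"),
                         activation_fraction = 0.7, flip_rate = 0.1,
                         missing_rate = 0.1,
                         mutation_mode = c("none", "match_expression",
                                           "random"),
                         n_samples = 4L, seed = 1L) {
  topology <- match.arg(topology)
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(n_genes >= 2L,
            activation_fraction >= 0, activation_fraction <= 1,
            flip_rate >= 0, flip_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            n_samples >= 1L)
  structure(list(n_genes = as.integer(n_genes), topology = topology,
                 activation_fraction = activation_fraction,
                 flip_rate = flip_rate, missing_rate = missing_rate,
                 mutation_mode = mutation_mode,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic pathway graph
#'
#' Deterministic given the spec's seed. Topologies: `chain` is a single
#' line; `tree` attaches each gene to a random earlier parent; `dag` is a
#' tree backbone plus random extra forward edges; `cyclic` is a dag plus at
#' least one back edge, so simple-path enumeration must truncate cycles.
#' Edge signs are activation with probability `activation_fraction`.
#'
#' @param spec a [fixture_spec()].
#' @return A [pathway_graph()].
#' @export
make_pathway <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_genes
  genes <- sprintf("G%02d", seq_len(n))
  with_seed(spec$seed, {
    edges <- switch(spec$topology,
      chain = data.frame(source = genes[-n], target = genes[-1L]),
      tree = data.frame(
        source = genes[vapply(2:n, function(i) sample.int(i - 1L, 1L),
                              integer(1))],
        target = genes[2:n]),
      dag = ,
      cyclic = {
        backbone <- data.frame(
          source = genes[vapply(2:n, function(i) sample.int(i - 1L, 1L),
                                integer(1))],
          target = genes[2:n])
        extra <- expand.grid(i = seq_len(n), j = seq_len(n))
        extra <- extra[extra$i < extra$j - 1L, , drop = FALSE]
        keep <- stats::runif(nrow(extra)) < 0.2
        fwd <- data.frame(source = genes[extra$i[keep]],
                          target = genes[extra$j[keep]])
        ed <- rbind(backbone, fwd)
        if (spec$topology == "cyclic") {
          back <- data.frame(source = genes[n], target = genes[1L])
          more <- extra[stats::runif(nrow(extra)) < 0.05, , drop = FALSE]
          ed <- rbind(ed, back,
                      data.frame(source = genes[more$j],
                                 target = genes[more$i]))
        }
        ed
      })
    edges <- unique(edges)
    edges$sign <- ifelse(stats::runif(nrow(edges)) <
                           spec$activation_fraction, 1L, -1L)
    pathway_graph(edges, name = sprintf("synthetic_%s_%d", spec$topology,
                                        spec$seed),
                  nodes = genes)
  })
}

#' Draw a null observation
#'
#' Each gene's expression is an independent fair coin (`+1`/`-1` with
#' probability 0.5); no mutation evidence. This is the null model the
#' significance machinery assumes.
#'
#' @param genes character vector of gene ids.
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return A [sample_observation()].
#' @export
sample_null_observation <- function(genes, seed = 1L,
                                    sample_id = "null") {
  stopifnot(length(genes) >= 1L)
  r <- with_seed(seed, sample(c(1L, -1L), length(genes), replace = TRUE))
  sample_observation(sample_id, stats::setNames(r, genes))
}

#' Draw an observation consistent with a route, with controlled noise
#'
#' Starts from the fully consistent expression pattern of the route
#' (propagating `root_state` through the edge signs), then independently
#' flips each non-root gene with probability `flip_rate`. The ground-truth
#' number of inconsistent edges of the flipped (pre-masking) vector is
#' recorded as attribute `k_true`, and the full flipped vector as attribute
#' `r_full`. Expression values are then masked missing with probability
#' `missing_rate`. Mutation evidence per `mutation_mode`:
#' `"match_expression"` sets `m = r` (pre-masking), which makes
#' [route_score()] equal [reduced_score()] at `K = k_true` exactly;
#' `"random"` observes a random `+1`/`-1` mutation on each gene with
#' probability 0.5; `"none"` leaves mutations empty.
#'
#' @param route a [route()].
#' @param root_state `+1` or `-1`.
#' @param flip_rate,missing_rate probabilities in `[0, 1]`.
#' @param mutation_mode see [fixture_spec()].
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return A [sample_observation()] with attributes `k_true` and `r_full`.
#' @export
sample_consistent_observation <- function(route, root_state = 1L,
                                          flip_rate = 0, missing_rate = 0,
                                          mutation_mode = c("none",
                                            "match_expression", "random"),
                                          seed = 1L,
                                          sample_id = "synthetic") {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(inherits(route, "route"), root_state %in% c(1L, -1L))
  w <- length(route$genes)
  with_seed(seed, {
    r <- expected_expression(route, as.integer(root_state))
    flip <- c(FALSE, stats::runif(w - 1L) < flip_rate)
    r[flip] <- -r[flip]
    k_true <- count_inconsistent_edges(route, r)
    m <- switch(mutation_mode,
      none = integer(),
      match_expression = stats::setNames(r, route$genes),
      random = {
        on <- stats::runif(w) < 0.5
        stats::setNames(sample(c(1L, -1L), w, replace = TRUE),
                        route$genes)[on]
      })
    r_obs <- r
    r_obs[stats::runif(w) < missing_rate] <- NA_integer_
    obs <- sample_observation(sample_id,
                              stats::setNames(r_obs, route$genes), m)
    attr(obs, "k_true") <- k_true
    attr(obs, "r_full") <- stats::setNames(r, route$genes)
    obs
  })
}

#' Generate a multi-sample observation set along a route
#'
#' One consistent-with-noise sample per `spec$n_samples`, with per-sample
#' seeds derived as `spec$seed + sample index`, so adding samples never
#' perturbs earlier ones.
#'
#' @param route a [route()].
#' @param spec a [fixture_spec()].
#' @return An [observation_set()].
#' @export
make_observation_set <- function(route, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  samples <- lapply(seq_len(spec$n_samples), function(i) {
    sample_consistent_observation(
      route, root_state = 1L, flip_rate = spec$flip_rate,
      missing_rate = spec$missing_rate,
      mutation_mode = spec$mutation_mode,
      seed = spec$seed + i, sample_id = sprintf("S%02d", i))
  })
  observation_set(samples)
}
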