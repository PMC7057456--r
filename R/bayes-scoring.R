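#' Scoring hyper-parameters
#'
#' The route-scoring model has four hyper-parameters:
#' \describe{
#'   \item{epsilon}{tolerated error rate in `(0, 0.5)`: the probability that
#'     a child gene contradicts a fully informative, consistent parent
#'     (mutation and expression agreeing). Each inconsistent edge penalizes
#'     the route score by a factor `epsilon/(1-epsilon)`.}
#'   \item{gamma}{mixed-evidence rate in `(epsilon, 0.5)`: the probability
#'     used when mutation and expression evidence at the parent conflict.}
#'   \item{t}{route-score threshold in `(0, 1]` above which a route counts
#'     as differentially regulated.}
#'   \item{alpha}{confidence level in `(0, 1)` for the calibration bound.}
#' }
#' The static default `epsilon = 0.1`, `gamma = 0.25` is a setting known to
#' behave well; [calibrate()] derives both dynamically from `t` and `alpha`.
#'
#' @param epsilon tolerated error rate.
#' @param gamma mixed-evidence rate.
#' @param t route-score threshold.
#' @param alpha confidence level.
#' @return An object of class `hyperparams`.
#' @examples
#' hyperparams()                  # static defaults
#' as_hyperparams(calibrate(10))  # dynamically calibrated
#' @export
hyperparams <- function(epsilon = 0.1, gamma = 0.25, t = 0.8, alpha = 0.05) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (!(epsilon > 0 && epsilon < 0.5)) {
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  }
  if (!(gamma > epsilon && gamma < 0.5)) {
    stop("gamma must lie in (epsilon, 0.5)", call. = FALSE)
  }
  if (!(t > 0 && t <= 1)) stop("t must lie in (0, 1]", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  structure(list(epsilon = epsilon, gamma = gamma, t = t, alpha = alpha),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf("<hyperparams> epsilon=%.4g gamma=%.4g t=%.4g alpha=%.4g\n",
              x$epsilon, x$gamma, x$t, x$alpha))
  invisible(x)
}

# P(child = +1 | mutation m, parent expression r) for one signed edge.
# Activation table:       m=+1,r=+1 -> 1-eps ; m=-1,r=+1 -> gamma
#                         m=+1,r=-1 -> 1-gamma ; m=-1,r=-1 -> eps
# Inhibition is the column-swapped mirror: P_inh(+1|.) = P_act(-1|.).
# Mutation evidence dominates expression when the two conflict.
edge_child_plus_prob <- function(sign, m, r_parent, hp) {
  n <- max(length(sign), length(m), length(r_parent))
  sign <- rep_len(sign, n)
  m <- rep_len(m, n)
  r_parent <- rep_len(r_parent, n)
  p_act <- ifelse(m == 1L,
                  ifelse(r_parent == 1L, 1 - hp$epsilon, 1 - hp$gamma),
                  ifelse(r_parent == 1L, hp$gamma, hp$epsilon))
  ifelse(sign == 1L, p_act, 1 - p_act)
}

#' Build the conditional probability table of one signed edge
#'
#' Returns the 4-row table giving `P(R_child | M_parent, R_parent)` for an
#' activation or inhibition edge. The inhibition table is the activation
#' table with its two output columns swapped.
#'
#' @param sign `+1` (activation) or `-1` (inhibition).
#' @param hp a [hyperparams()] object.
#' @return An object of class `edge_cpt`: a 4 x 2 numeric matrix with rows
#'   named by the parent configuration (`m`, `r`) and columns `"+1"`,
#'   `"-1"` for the child state.
#' @examples
#' build_edge_cpt(1, hyperparams())
#' @export
build_edge_cpt <- function(sign, hp = hyperparams()) {
  sign <- as.integer(sign)
  if (!sign %in% c(1L, -1L)) stop("sign must be +1 or -1", call. = FALSE)
  stopifnot(inherits(hp, "hyperparams"))
  combos <- data.frame(m = c(1L, -1L, 1L, -1L), r = c(1L, 1L, -1L, -1L))
  p <- edge_child_plus_prob(sign, combos$m, combos$r, hp)
  tab <- cbind(`+1` = p, `-1` = 1 - p)
  rownames(tab) <- sprintf("m=%+d,r=%+d", combos$m, combos$r)
  structure(tab, sign = sign, class = c("edge_cpt", class(tab)))
}

#' Marginal child probability of an edge with unknown mutation
#'
#' Averages the edge CPT over a uniform mutation prior:
#' for activation with parent `+1` this is `(1 + gamma - epsilon)/2`, which
#' exceeds 0.5 whenever `gamma > epsilon` so that consistent propagation is
#' always favoured.
#'
#' @param sign `+1` or `-1`.
#' @param parent_state parent expression state, `+1` or `-1`.
#' @param hp a [hyperparams()] object.
#' @return `P(child = +1 | parent)` as a number.
#' @export
marginal_edge_prob <- function(sign, parent_state, hp = hyperparams()) {
  stopifnot(inherits(hp, "hyperparams"))
  0.5 * edge_child_plus_prob(sign, 1L, parent_state, hp) +
    0.5 * edge_child_plus_prob(sign, -1L, parent_state, hp)
}

#' Expected expression propagated along a route
#'
#' The interpretation logic: assuming the root gene is in state
#' `assumed_root`, every activation edge copies the parent's state to the
#' child and every inhibition edge flips it, so the expected state vector is
#' the cumulative product of the edge signs.
#'
#' @param route a [route()].
#' @param assumed_root root state, `+1` (default) or `-1`.
#' @return Integer vector of expected states, one per route gene.
#' @examples
#' expected_expression(route(c("A", "B", "C"), c(1, -1)))
#' @export
expected_expression <- function(route, assumed_root = 1L) {
  stopifnot(inherits(route, "route"), assumed_root %in% c(1L, -1L))
  as.integer(cumprod(c(as.integer(assumed_root), route$signs)))
}

#' Transform a route into its Bayesian network
#'
#' Given a route of `w` genes the network has `w` expression variables
#' `R_1..R_w` and `w - 1` mutation variables `M_1..M_{w-1}`; each `R_{j+1}`
#' has exactly the parents `R_j` and `M_j` with the CPT of the j-th edge,
#' the root expression prior is uniform and each mutation prior is uniform.
#'
#' @param route a [route()].
#' @param hp a [hyperparams()] object.
#' @return An object of class `route_bayes_net` with fields `route`, `hp`,
#'   `cpts` (one [build_edge_cpt()] per edge), `root_prior` and
#'   `mutation_prior`.
#' @export
route_to_bayes_net <- function(route, hp = hyperparams()) {
  stopifnot(inherits(route, "route"), inherits(hp, "hyperparams"))
  structure(list(route = route, hp = hp,
                 cpts = lapply(route$signs, build_edge_cpt, hp = hp),
                 root_prior = c(`+1` = 0.5, `-1` = 0.5),
                 mutation_prior = c(`+1` = 0.5, `-1` = 0.5)),
            class = "route_bayes_net")
}

#' Joint probability of a full assignment under a route Bayesian network
#'
#' Mainly for inspection and exhaustive-enumeration checks; scoring uses the
#' forward recursion in [route_score()].
#'
#' @param net a [route_to_bayes_net()].
#' @param r integer vector of expression states (`+1`/`-1`), one per gene.
#' @param m integer vector of mutation states (`+1`/`-1`), one per edge.
#' @return The joint probability `P(R = r, M = m)`.
#' @export
bayes_net_joint <- function(net, r, m) {
  stopifnot(inherits(net, "route_bayes_net"))
  w <- length(net$route$genes)
  stopifnot(length(r) == w, length(m) == w - 1L,
            all(r %in% c(1L, -1L)), all(m %in% c(1L, -1L)))
  hp <- net$hp
  p <- 0.5 * 0.5^(w - 1L)  # root + mutation priors, all uniform
  for (j in seq_len(w - 1L)) {
    pp <- edge_child_plus_prob(net$route$signs[j], m[j], r[j], hp)
    p <- p * if (r[j + 1L] == 1L) pp else 1 - pp
  }
  p
}

# Scaled forward recursion over the chain-shaped network: returns
# log P(evidence), summing out missing expression states and unobserved
# mutations. r_ev / m_ev use NA for "not observed". Per-step rescaling keeps
# long routes away from underflow.
forward_log_prob <- function(r_ev, m_ev, signs, hp) {
  states <- c(1L, -1L)
  alpha <- c(0.5, 0.5)
  if (!is.na(r_ev[1L])) alpha[states != r_ev[1L]] <- 0
  log_scale <- 0
  for (j in seq_along(signs)) {
    new <- numeric(2L)
    for (yi in 1:2) {
      y <- states[yi]
      trans <- numeric(2L)
      for (xi in 1:2) {
        x <- states[xi]
        trans[xi] <- if (is.na(m_ev[j])) {
          pp <- marginal_edge_prob(signs[j], x, hp)
          if (y == 1L) pp else 1 - pp
        } else {
          pp <- edge_child_plus_prob(signs[j], m_ev[j], x, hp)
          0.5 * (if (y == 1L) pp else 1 - pp)  # 0.5 = mutation prior
        }
      }
      new[yi] <- sum(alpha * trans)
    }
    if (!is.na(r_ev[j + 1L])) new[states != r_ev[j + 1L]] <- 0
    s <- sum(new)
    if (s <= 0) return(-Inf)
    log_scale <- log_scale + log(s)
    alpha <- new / s
  }
  log_scale + log(sum(alpha))
}

# Align a sample observation with a route: expression per gene, mutation per
# edge (the mutation variable of edge j belongs to the parent gene j).
route_evidence <- function(route, obs) {
  stopifnot(inherits(route, "route"), inherits(obs, "sample_observation"))
  w <- length(route$genes)
  r_ev <- rep(NA_integer_, w)
  hit <- match(route$genes, names(obs$r))
  r_ev[!is.na(hit)] <- obs$r[hit[!is.na(hit)]]
  m_ev <- rep(NA_integer_, w - 1L)
  hit <- match(route$genes[-w], names(obs$m))
  m_ev[!is.na(hit)] <- obs$m[hit[!is.na(hit)]]
  list(r = r_ev, m = m_ev)
}

#' Score a route against one sample
#'
#' The route score is the probability of the observed evidence under the
#' route's Bayesian network, normalized by the probability of the fully
#' consistent observation with the same pattern of available data:
#' expression values are replaced by the consistent configuration anchored
#' at the first observed gene's state (propagated by the edge signs), and
#' observed mutation states by the consistent expression of their gene.
#' Missing expression values and unobserved mutations are summed out
#' identically in numerator and denominator. The score is 1 exactly when
#' the observation is fully consistent and decays towards 0 with each
#' inconsistent edge; when every mutation is observed and equals its gene's
#' expression it equals the closed form `(epsilon/(1-epsilon))^K` of
#' [reduced_score()], where `K` counts inconsistent edges.
#'
#' @param route a [route()].
#' @param obs a [sample_observation()].
#' @param hp a [hyperparams()] object.
#' @return A number in `(0, 1]`.
#' @seealso [signed_score()], [reduced_score()], [score_route()]
#' @export
route_score <- function(route, obs, hp = hyperparams()) {
  ev <- route_evidence(route, obs)
  obs_pos <- which(!is.na(ev$r))
  if (length(obs_pos) < 2L) {
    stop(undefined_score_condition(route))
  }
  rstar <- consistent_assignment(route, ev, obs_pos[1L])
  num <- forward_log_prob(ev$r, ev$m, route$signs, hp)
  den <- forward_log_prob(ifelse(is.na(ev$r), NA_integer_, rstar),
                          ifelse(is.na(ev$m), NA_integer_,
                                 rstar[-length(rstar)]),
                          route$signs, hp)
  exp(num - den)
}

# fully consistent expression configuration anchored so that the first
# observed gene keeps its observed value
consistent_assignment <- function(route, ev, anchor_pos) {
  rdot <- expected_expression(route, 1L)
  as.integer(rdot * (ev$r[anchor_pos] * rdot[anchor_pos]))
}

undefined_score_condition <- function(route) {
  structure(class = c("routescore_undefined_score", "error", "condition"),
            list(message = sprintf(
              "route %s has fewer than two observed genes; score undefined",
              route_id(route)),
              call = NULL))
}

#' Signed route score
#'
#' The route score with a direction attached: positive (activated) when the
#' last observed gene on the route is in the state predicted by propagating
#' `+1` from the root through the edge signs, negative (suppressed)
#' otherwise. A consistent but globally down-regulated route therefore
#' scores `-1`. Trailing genes with missing expression are skipped; the
#' sign is read at the last gene that was actually observed.
#'
#' @inheritParams route_score
#' @return A number in `[-1, 1]` whose absolute value is [route_score()].
#' @export
signed_score <- function(route, obs, hp = hyperparams()) {
  ev <- route_evidence(route, obs)
  obs_pos <- which(!is.na(ev$r))
  if (length(obs_pos) < 2L) stop(undefined_score_condition(route))
  last <- obs_pos[length(obs_pos)]
  rdot <- expected_expression(route, 1L)
  sgn <- if (ev$r[last] == rdot[last]) 1 else -1
  sgn * route_score(route, obs, hp)
}

#' Full per-route result for one sample
#'
#' Convenience wrapper computing score, signed score and direction in one
#' pass.
#'
#' @inheritParams route_score
#' @return An object of class `route_result`: list with `route`, `score`,
#'   `s_score` and `direction` (`"activated"` or `"suppressed"`).
#' @export
score_route <- function(route, obs, hp = hyperparams()) {
  s <- signed_score(route, obs, hp)
  structure(list(route = route, score = abs(s), s_score = s,
                 direction = if (s >= 0) "activated" else "suppressed"),
            class = "route_result")
}

#' @export
print.route_result <- function(x, ...) {
  cat(sprintf("<route_result> %s: score=%.4g s_score=%+.4g (%s)\n",
              route_id(x$route), x$score, x$s_score, x$direction))
  invisible(x)
}

#' Reduced route score from the inconsistent-edge count
#'
#' Closed form of the route score when mutation evidence is present and
#' matches the expression at every gene: each of the `K` inconsistent edges
#' contributes a factor `epsilon/(1-epsilon)` and consistent edges
#' contribute 1, giving `(epsilon/(1-epsilon))^K`.
#'
#' @param K number of inconsistent edges (vectorized).
#' @param n_edges total number of route edges.
#' @param hp a [hyperparams()] object.
#' @return Numeric vector of scores in `(0, 1]`.
#' @examples
#' reduced_score(0:3, 3, hyperparams(epsilon = 0.1, gamma = 0.25))
#' @export
reduced_score <- function(K, n_edges, hp = hyperparams()) {
  stopifnot(inherits(hp, "hyperparams"))
  K <- as.integer(K)
  n_edges <- as.integer(n_edges)
  if (any(K < 0L | K > n_edges)) {
    stop("K must lie in [0, n_edges]", call. = FALSE)
  }
  (hp$epsilon / (1 - hp$epsilon))^K
}

#' Count inconsistent edges of a fully observed route
#'
#' An edge is inconsistent when the child's observed state differs from the
#' parent's state multiplied by the edge sign.
#'
#' @param route a [route()].
#' @param r integer vector of expression states (`+1`/`-1`), one per route
#'   gene, no missing values.
#' @return Integer count `K`.
#' @export
count_inconsistent_edges <- function(route, r) {
  stopifnot(inherits(route, "route"))
  w <- length(route$genes)
  stopifnot(length(r) == w, all(r %in% c(1L, -1L)))
  sum(r[-1L] != r[-w] * route$signs)
}
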