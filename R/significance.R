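#' Null consistency probability of a route
#'
#' Under the null model each gene's expression is an independent fair coin.
#' A route of `w` genes is fully consistent for exactly two of the `2^w`
#' equally likely assignments (one per root state), so the probability that
#' a random observation is fully consistent is `0.5^(w-1)`. Mutation
#' evidence is sparse and treated as a fixed prior parameter, not as part of
#' the randomness.
#'
#' @param route a [route()], or directly the number of genes `w`.
#' @return `0.5^(w-1)`.
#' @examples
#' route_sig_score(5)   # 0.0625
#' @export
route_sig_score <- function(route) {
  w <- if (inherits(route, "route")) length(route$genes)
       else as.integer(route)
  stopifnot(length(w) == 1L, w >= 1L)
  0.5^(w - 1L)
}

#' Length-weighted pathway score
#'
#' Fraction of a pathway's routes that are differentially regulated,
#' weighting each route by its length in genes: a route counts when its
#' mean unsigned score over the samples reaches the threshold `t` of `hp`.
#' Per-sample scores that are undefined (fewer than two observed genes on
#' the route) are dropped from the mean; a route with no scorable sample is
#' excluded from both sums.
#'
#' @param routes list of [route()] objects.
#' @param obs_set an [observation_set()].
#' @param hp a [hyperparams()] object (threshold `t` is taken from it).
#' @param hp_fun optional function mapping a route length (genes) to a
#'   [hyperparams()] object, enabling per-route-length calibration; when
#'   given it overrides `hp` for scoring (the threshold still comes from
#'   `hp$t`).
#' @return The pathway score in `[0, 1]`, with attribute `per_route`, a data
#'   frame of per-route mean scores and pass indicators.
#' @export
pathway_score <- function(routes, obs_set, hp = hyperparams(),
                          hp_fun = NULL) {
  stopifnot(inherits(obs_set, "observation_set"))
  tol <- 1e-9
  per <- lapply(routes, function(rt) {
    hp_rt <- if (is.null(hp_fun)) hp else hp_fun(length(rt$genes))
    scores <- vapply(obs_set$samples, function(s) {
      tryCatch(route_score(rt, s, hp_rt),
               routescore_undefined_score = function(e) NA_real_)
    }, numeric(1))
    scores <- scores[!is.na(scores)]
    data.frame(route_id = route_id(rt), length = length(rt$genes),
               n_scored = length(scores),
               mean_score = if (length(scores)) mean(scores) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  scorable <- per[per$n_scored > 0L, , drop = FALSE]
  if (nrow(scorable) == 0L) {
    stop(structure(class = c("routescore_undefined_score", "error",
                             "condition"),
                   list(message = "no scorable routes in pathway",
                        call = NULL)))
  }
  per$passes <- !is.na(per$mean_score) & per$mean_score >= hp$t - tol
  p <- sum(per$length[per$passes]) / sum(per$length[per$n_scored > 0L])
  structure(p, per_route = per)
}

#' Exact Poisson-binomial probability mass function
#'
#' Probability of `q` successes among independent Bernoulli trials with
#' heterogeneous success probabilities, by dynamic-programming convolution.
#' Serves as the exact reference for the binomial approximation used in
#' [pathway_sig_score()].
#'
#' @param success_probs numeric vector of probabilities in `[0, 1]`.
#' @param q number of successes (vectorized); values outside `[0, k]` give
#'   probability 0.
#' @return `P(Q = q)`.
#' @examples
#' poisson_binomial_pmf(c(0.1, 0.9), 1)   # 0.82
#' @export
poisson_binomial_pmf <- function(success_probs, q) {
  stopifnot(is.numeric(success_probs),
            all(success_probs >= 0 & success_probs <= 1))
  f <- 1
  for (p in success_probs) {
    f <- c(f * (1 - p), 0) + c(0, f * p)
  }
  k <- length(success_probs)
  q <- as.integer(q)
  out <- numeric(length(q))
  ok <- q >= 0L & q <= k
  out[ok] <- f[q[ok] + 1L]
  out
}

#' Pathway-level significance of the observed route-consistency count
#'
#' The number `Q` of routes that come out differentially regulated when all
#' expression observations are random fair coins follows a Poisson-binomial
#' distribution over the routes' null consistency probabilities; it is
#' approximated by `Binomial(k, mu/k)` with `k` the route count and `mu` the
#' Poisson-binomial mean, `mu = sum over routes of the product over samples
#' of the route's null consistency probability` ([route_sig_score()], which
#' does not depend on the data). The reported value is the PMF at the
#' observed count `q`; low values mean the observed configuration is
#' unlikely under the null, i.e. significant. An upper-tail variant
#' `P(Q >= q)` is available via `upper_tail = TRUE`.
#'
#' @param routes list of [route()] objects (`k = length(routes)`).
#' @param obs_set an [observation_set()]; only the number of samples enters
#'   the null model.
#' @param q observed count of differentially regulated routes; defaults to
#'   the number of routes whose mean unsigned score reaches `hp$t`,
#'   mirroring the [pathway_score()] indicator.
#' @param hp a [hyperparams()] object (used only when `q` is derived).
#' @param upper_tail report `P(Q >= q)` instead of the point mass.
#' @return A probability, with attributes `q`, `k` and `mu`.
#' @export
pathway_sig_score <- function(routes, obs_set, q = NULL,
                              hp = hyperparams(), upper_tail = FALSE) {
  stopifnot(inherits(obs_set, "observation_set"))
  k <- length(routes)
  if (k < 1L) stop("need at least one route", call. = FALSE)
  n_samples <- length(obs_set$samples)
  mu <- sum(vapply(routes,
                   function(rt) route_sig_score(rt)^n_samples,
                   numeric(1)))
  if (is.null(q)) {
    ps <- pathway_score(routes, obs_set, hp)
    q <- sum(attr(ps, "per_route")$passes)
  }
  q <- as.integer(q)
  if (q < 0L || q > k) stop("q must lie in [0, k]", call. = FALSE)
  p <- mu / k
  if (p > 1) {
    warning("mu/k exceeds 1; clamped", call. = FALSE)
    p <- 1
  }
  val <- if (upper_tail) {
    stats::pbinom(q - 1L, k, p, lower.tail = FALSE)
  } else {
    stats::dbinom(q, k, p)
  }
  structure(val, q = q, k = k, mu = mu)
}

#' Summarize a pathway against an observation set
#'
#' Enumerates nothing itself: takes the route set as given (see
#' [enumerate_all_routes()]), and reports the pathway score, the observed
#' differentially-regulated count and the pathway significance.
#'
#' @param name pathway name.
#' @param routes list of [route()] objects.
#' @param obs_set an [observation_set()].
#' @param hp a [hyperparams()] object.
#' @param hp_fun optional per-route-length hyper-parameter rule, see
#'   [pathway_score()].
#' @return An object of class `pathway_result`: list with `pathway`,
#'   `p_score`, `sig_score`, `q`, `n_routes` and `per_route` (data frame).
#' @export
pathway_result <- function(name, routes, obs_set, hp = hyperparams(),
                           hp_fun = NULL) {
  ps <- pathway_score(routes, obs_set, hp, hp_fun = hp_fun)
  per <- attr(ps, "per_route")
  q <- sum(per$passes)
  sig <- pathway_sig_score(routes, obs_set, q = q, hp = hp)
  structure(list(pathway = name, p_score = as.numeric(ps),
                 sig_score = as.numeric(sig), q = q,
                 n_routes = length(routes), per_route = per),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("<pathway_result> %s: pScore=%.4g SigScore=%.4g (q=%d of %d routes)\n",
              x$pathway, x$p_score, x$sig_score, x$q, x$n_routes))
  invisible(x)
}
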