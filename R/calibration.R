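#' Lower-tail quantile of the null inconsistent-edge distribution
#'
#' Under the null hypothesis each route edge is independently inconsistent
#' with probability 0.5, so the inconsistent-edge count `K` over `n_edges`
#' edges is `Binomial(n_edges, 0.5)`. The exact method returns the largest
#' integer `q` whose CDF does not exceed `alpha` — the conservative choice
#' that never violates the level. The normal method returns the continuous
#' quantile of the normal approximation,
#' `0.5 * n_edges + z_alpha * 0.5 * sqrt(n_edges)`, which offers arbitrary
#' levels but can violate the guarantee on short routes.
#'
#' @param n_edges number of route edges (>= 1).
#' @param alpha level in `(0, 1)`.
#' @param method `"exact"` (default) or `"normal"`.
#' @return The quantile; `NA` when even `K = 0` has CDF above `alpha`
#'   (exact method), signalling that no valid quantile exists.
#' @examples
#' null_quantile_q_alpha(9, 0.05)              # 1
#' null_quantile_q_alpha(9, 0.05, "normal")    # about 2.03
#' @export
null_quantile_q_alpha <- function(n_edges, alpha,
                                  method = c("exact", "normal")) {
  method <- match.arg(method)
  n_edges <- as.integer(n_edges)
  stopifnot(n_edges >= 1L, alpha > 0, alpha < 1)
  if (method == "normal") {
    return(0.5 * n_edges + stats::qnorm(alpha) * 0.5 * sqrt(n_edges))
  }
  qs <- 0:n_edges
  cdf <- stats::pbinom(qs, n_edges, 0.5)
  ok <- qs[cdf <= alpha + 1e-12]
  if (length(ok) == 0L) return(NA_integer_)
  max(ok)
}

#' Upper bound on the tolerated error rate
#'
#' For a route with `n_edges` edges and threshold `t` in `(0, 1)`, choosing
#' `epsilon <= B(t, alpha) = 1 - 1/(1 + t^(1/q_alpha))` guarantees that the
#' probability of a null route score reaching `t` stays below `alpha`
#' (exact-quantile method): the reduced score `(epsilon/(1-epsilon))^K`
#' reaches `t` only for `K <= q_alpha`, an event of null probability at most
#' `alpha`. The bound increases in both `t` and `alpha` and always lies in
#' `(0, 0.5)`. At `t = 1` no finite bound applies — only fully consistent
#' routes (`K = 0`) qualify regardless of `epsilon` — so this function
#' requires `t < 1`; see [calibrate()] for the strict regime.
#'
#' When no valid quantile exists (routes so short that even `K = 0` is
#' likelier than `alpha`), the static default `epsilon = 0.1` is returned
#' with a warning.
#'
#' @param t route-score threshold in `(0, 1)`.
#' @param alpha level in `(0, 1)`.
#' @param n_edges number of route edges.
#' @param method quantile method, see [null_quantile_q_alpha()].
#' @return The calibrated `epsilon` in `(0, 0.5)`.
#' @examples
#' epsilon_bound(0.8, 0.05, 9)   # 4/9
#' @export
epsilon_bound <- function(t, alpha, n_edges,
                          method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(t > 0, t < 1, alpha > 0, alpha < 1)
  q <- null_quantile_q_alpha(n_edges, alpha, method)
  if (is.na(q) || q <= 0) {
    warning(sprintf(
      "no valid null quantile for %d edge(s) at alpha=%g; falling back to epsilon=0.1",
      n_edges, alpha), call. = FALSE)
    return(0.1)
  }
  1 - 1 / (1 + t^(1 / q))
}

#' Derive gamma from epsilon
#'
#' The mixed-evidence rate is set to the midpoint of the admissible interval
#' `(epsilon, 0.5)`, i.e. `(epsilon + 0.5)/2`, which penalizes
#' mutation/expression conflicts more than plain errors while staying below
#' the uninformative 0.5.
#'
#' @param epsilon error rate in `(0, 0.5)`.
#' @return `gamma = (epsilon + 0.5)/2`.
#' @export
gamma_from_epsilon <- function(epsilon) {
  if (!(is.numeric(epsilon) && all(epsilon > 0 & epsilon < 0.5))) {
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  }
  (epsilon + 0.5) / 2
}

#' Calibrate hyper-parameters for a route length
#'
#' Composes the null quantile, the epsilon bound and the gamma rule into a
#' full hyper-parameter setting for routes of `route_length` genes
#' (`route_length - 1` edges). With the exact quantile the guarantee
#' `P(null route score >= t) < alpha` holds by construction. `t = 1` is the
#' strict-consistency regime: no finite bound exists and the static default
#' is used for the CPTs while only `K = 0` routes can reach the threshold.
#' For very short routes no valid quantile exists and the static default
#' `epsilon = 0.1`, `gamma = 0.25` is used.
#'
#' @param route_length number of genes on the route (>= 2).
#' @param t route-score threshold; default 0.8.
#' @param alpha level; default 0.05.
#' @param method quantile method, see [null_quantile_q_alpha()].
#' @return An object of class `calibration_result`: list with `n_edges`,
#'   `q_alpha`, `epsilon`, `gamma`, `t`, `alpha`, `method`, `strict`
#'   (TRUE iff `t == 1`) and `fallback` (TRUE when the static default was
#'   used).
#' @examples
#' calibrate(10)   # epsilon = 4/9, gamma approx 0.472
#' @export
calibrate <- function(route_length, t = 0.8, alpha = 0.05,
                      method = c("exact", "normal")) {
  method <- match.arg(method)
  route_length <- as.integer(route_length)
  stopifnot(route_length >= 2L, t > 0, t <= 1, alpha > 0, alpha < 1)
  n_edges <- route_length - 1L
  strict <- t == 1
  if (strict) {
    q <- NA_real_
    epsilon <- 0.1
    fallback <- TRUE
  } else {
    q <- null_quantile_q_alpha(n_edges, alpha, method)
    if (is.na(q) || q <= 0) {
      epsilon <- 0.1
      fallback <- TRUE
    } else {
      epsilon <- 1 - 1 / (1 + t^(1 / q))
      fallback <- FALSE
    }
  }
  gamma <- if (fallback) 0.25 else gamma_from_epsilon(epsilon)
  structure(list(n_edges = n_edges, q_alpha = q, epsilon = epsilon,
                 gamma = gamma, t = t, alpha = alpha, method = method,
                 strict = strict, fallback = fallback),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d edge(s), t=%g alpha=%g (%s): q_alpha=%s epsilon=%.4g gamma=%.4g%s%s\n",
    x$n_edges, x$t, x$alpha, x$method,
    format(x$q_alpha), x$epsilon, x$gamma,
    if (x$strict) " [strict: only K=0 qualifies]" else "",
    if (x$fallback && !x$strict) " [fallback to static default]" else ""))
  invisible(x)
}

#' Convert a calibration result to hyper-parameters
#'
#' @param cal a [calibrate()] result.
#' @return A [hyperparams()] object carrying the calibrated `epsilon` and
#'   `gamma` together with the calibration's `t` and `alpha`.
#' @export
as_hyperparams <- function(cal) {
  stopifnot(inherits(cal, "calibration_result"))
  hyperparams(epsilon = cal$epsilon, gamma = cal$gamma, t = cal$t,
              alpha = cal$alpha)
}

#' Simulate the null exceedance rate of calibrated route scores
#'
#' Monte-Carlo check of the calibration guarantee: draw `n_reps` null routes
#' with each of `n_edges` edges independently inconsistent with probability
#' 0.5, score each with the reduced formula under the calibrated `epsilon`,
#' and report the fraction of scores reaching the threshold `t`. With the
#' exact quantile this fraction stays below `alpha` up to Monte-Carlo noise.
#'
#' @param n_edges number of route edges; default 9.
#' @param t threshold; default 0.8.
#' @param alpha level; default 0.05.
#' @param n_reps number of replicates; default 10000.
#' @param seed integer seed.
#' @param method quantile method.
#' @return A list with the calibration, `exceedance` (fraction in `[0, 1]`),
#'   `n_reps` and `seed`.
#' @export
null_exceedance <- function(n_edges = 9L, t = 0.8, alpha = 0.05,
                            n_reps = 10000L, seed = 1L,
                            method = c("exact", "normal")) {
  method <- match.arg(method)
  cal <- calibrate(n_edges + 1L, t = t, alpha = alpha, method = method)
  hp <- as_hyperparams(cal)
  k_draws <- with_seed(seed, stats::rbinom(n_reps, n_edges, 0.5))
  scores <- reduced_score(k_draws, n_edges, hp)
  exceed <- mean(scores >= t - 1e-9)
  list(calibration = cal, exceedance = exceed, n_reps = n_reps,
       seed = seed)
}
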