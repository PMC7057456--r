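hp_ref <- hyperparams(epsilon = 0.1, gamma = 0.25)

test_that("edge CPTs carry the activation/inhibition logic", {
  act <- build_edge_cpt(1L, hp_ref)
  inh <- build_edge_cpt(-1L, hp_ref)
  expect_equal(act["m=+1,r=+1", "+1"], 0.9)   # 1 - eps
  expect_equal(act["m=-1,r=+1", "+1"], 0.25)  # gamma
  expect_equal(act["m=+1,r=-1", "+1"], 0.75)  # 1 - gamma
  expect_equal(act["m=-1,r=-1", "+1"], 0.1)   # eps
  expect_equal(inh["m=-1,r=-1", "+1"], 0.9)   # mirror row
  # rows sum to one, inhibition is the column swap of activation
  expect_equal(unname(rowSums(act)), rep(1, 4))
  expect_equal(unname(inh[, "+1"]), unname(act[, "-1"]))
  expect_error(build_edge_cpt(0L), "sign")

  # near-zero error rate approaches the deterministic limit
  tiny <- hyperparams(epsilon = 1e-9, gamma = 0.25)
  expect_equal(build_edge_cpt(1L, tiny)["m=+1,r=+1", "+1"], 1,
               tolerance = 1e-8)
})

test_that("marginal edge probabilities average the CPT over mutations", {
  expect_equal(marginal_edge_prob(1L, 1L, hp_ref), 0.575)   # (1+g-e)/2
  expect_equal(marginal_edge_prob(-1L, 1L, hp_ref), 0.425)
  # consistent propagation always beats a coin flip since gamma > eps
  for (e in c(0.05, 0.2, 0.4)) {
    hp <- hyperparams(e, gamma_from_epsilon(e))
    expect_gt(marginal_edge_prob(1L, 1L, hp), 0.5)
    expect_gt(marginal_edge_prob(-1L, -1L, hp), 0.5)
  }
})

test_that("expected expression is the cumulative product of edge signs", {
  expect_equal(expected_expression(route(c("A", "B", "C"), c(1L, 1L))),
               c(1L, 1L, 1L))
  expect_equal(expected_expression(route(c("A", "B", "C"), c(1L, -1L))),
               c(1L, 1L, -1L))
  for (seed in 1:5) {
    rt <- random_route(6, seed)
    expect_equal(expected_expression(rt, -1L), -expected_expression(rt, 1L))
  }
})

test_that("route Bayesian networks have the prescribed shape and normalize", {
  rt2 <- route(c("A", "B"), 1L)
  net2 <- route_to_bayes_net(rt2, hp_ref)
  expect_length(net2$cpts, 1L)
  rt4 <- random_route(4, seed = 2)
  net4 <- route_to_bayes_net(rt4, hp_ref)
  expect_length(net4$cpts, 3L)  # 4 expression + 3 mutation variables

  # joint sums to 1 over all 2^(2w-1) assignments
  w <- 4L
  grid <- do.call(expand.grid, rep(list(c(1L, -1L)), 2L * w - 1L))
  total <- sum(apply(grid, 1, function(a) {
    bayes_net_joint(net4, as.integer(a[1:w]),
                    as.integer(a[(w + 1):(2 * w - 1)]))
  }))
  expect_equal(total, 1)
})

test_that("consistent observations score exactly one", {
  for (seed in 1:10) {
    rt <- random_route(sample(2:8, 1), seed)
    for (root in c(1L, -1L)) {
      r <- expected_expression(rt, root)
      obs <- sample_observation("s", stats::setNames(r, rt$genes),
                                stats::setNames(r, rt$genes))
      expect_identical(route_score(rt, obs, hp_ref), 1)
      obs_nomut <- sample_observation("s", stats::setNames(r, rt$genes))
      expect_identical(route_score(rt, obs_nomut, hp_ref), 1)
    }
  }
})

test_that("with matching mutation evidence the score is (eps/(1-eps))^K", {
  for (seed in 1:20) {
    set.seed(seed)
    w <- sample(3:9, 1)
    rt <- random_route(w, seed + 100)
    r <- expected_expression(rt, 1L)
    flip <- which(runif(w - 1L) < 0.4) + 1L
    r[flip] <- -r[flip]
    k <- count_inconsistent_edges(rt, r)
    obs <- sample_observation("s", stats::setNames(r, rt$genes),
                              stats::setNames(r, rt$genes))
    expect_equal(route_score(rt, obs, hp_ref),
                 (0.1 / 0.9)^k, tolerance = 1e-12)
  }
})

test_that("scores match exhaustive joint-probability enumeration", {
  for (seed in 1:12) {
    set.seed(seed)
    w <- sample(3:6, 1)
    rt <- random_route(w, seed + 500)
    # random evidence: r with occasional missing, m observed sporadically
    r <- sample(c(1L, -1L, NA_integer_), w, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    if (sum(!is.na(r)) < 2L) r[1:2] <- c(1L, -1L)
    m <- sample(c(1L, -1L, NA_integer_), w, replace = TRUE,
                prob = c(0.25, 0.25, 0.5))
    obs <- sample_observation("s", stats::setNames(r, rt$genes),
                              stats::setNames(m, rt$genes)[!is.na(m)])
    e <- runif(1, 0.02, 0.45)
    hp <- hyperparams(e, gamma_from_epsilon(e))
    expect_equal(route_score(rt, obs, hp), oracle_route_score(rt, obs, hp),
                 tolerance = 1e-12, info = sprintf("seed %d", seed))
  }
})

test_that("a missing middle gene is marginalized over both completions", {
  rt <- route(c("A", "B", "C"), c(1L, 1L))
  obs <- sample_observation("s", c(A = 1L, B = NA, C = 1L))
  expect_equal(route_score(rt, obs, hp_ref),
               oracle_route_score(rt, obs, hp_ref), tolerance = 1e-12)
  obs_bad <- sample_observation("s", c(A = 1L, B = NA, C = -1L))
  expect_lt(route_score(rt, obs_bad, hp_ref), 1)
  expect_equal(route_score(rt, obs_bad, hp_ref),
               oracle_route_score(rt, obs_bad, hp_ref), tolerance = 1e-12)
})

test_that("each additional inconsistent edge strictly lowers the score", {
  rt <- random_route(7, seed = 9)
  w <- length(rt$genes)
  # propagate from the root but invert the first `nbreak` edges, so the
  # observation has exactly nbreak inconsistent edges
  with_breaks <- function(nbreak) {
    r <- 1L
    for (j in seq_len(w - 1L)) {
      r[j + 1L] <- r[j] * rt$signs[j] * (if (j <= nbreak) -1L else 1L)
    }
    r
  }
  for (mutated in c(TRUE, FALSE)) {
    prev <- Inf
    for (nbreak in 0:4) {
      r <- with_breaks(nbreak)
      expect_equal(count_inconsistent_edges(rt, r), nbreak)
      m <- if (mutated) stats::setNames(r, rt$genes) else integer()
      obs <- sample_observation("s", stats::setNames(r, rt$genes), m)
      sc <- route_score(rt, obs, hp_ref)
      expect_lt(sc, prev)
      expect_gt(sc, 0)
      expect_lte(sc, 1)
      prev <- sc
    }
  }
})

test_that("signed score carries direction and negation antisymmetry", {
  rt <- route(c("A", "B", "C"), c(1L, 1L))
  up <- sample_observation("s", c(A = 1L, B = 1L, C = 1L))
  down <- sample_observation("s", c(A = -1L, B = -1L, C = -1L))
  expect_identical(signed_score(rt, up, hp_ref), 1)
  expect_identical(signed_score(rt, down, hp_ref), -1)
  expect_equal(score_route(rt, down, hp_ref)$direction, "suppressed")

  # without mutation evidence, negating the observation flips the sign only
  for (seed in 1:8) {
    set.seed(seed)
    rt <- random_route(4, seed + 40)
    r <- sample(c(1L, -1L), 4, replace = TRUE)
    o1 <- sample_observation("s", stats::setNames(r, rt$genes))
    o2 <- sample_observation("s", stats::setNames(-r, rt$genes))
    expect_equal(signed_score(rt, o1, hp_ref) + signed_score(rt, o2, hp_ref),
                 0, tolerance = 1e-12)
  }

  # flipping only the last observed state flips the sign, keeps magnitude rule
  r <- c(A = 1L, B = 1L, C = 1L)
  s1 <- signed_score(rt <- route(c("A", "B", "C"), c(1L, 1L)),
                     sample_observation("s", r), hp_ref)
  r["C"] <- -1L
  s2 <- signed_score(rt, sample_observation("s", r), hp_ref)
  expect_gt(s1, 0)
  expect_lt(s2, 0)

  # trailing missing values are skipped, not fatal
  obs_trail <- sample_observation("s", c(A = 1L, B = 1L, C = NA))
  expect_identical(signed_score(rt, obs_trail, hp_ref), 1)
})

test_that("undefined scores raise a typed condition", {
  rt <- route(c("A", "B", "C"), c(1L, 1L))
  obs <- sample_observation("s", c(A = 1L, B = NA, C = NA))
  expect_error(route_score(rt, obs, hp_ref),
               class = "routescore_undefined_score")
})

test_that("reduced score follows the closed form and is monotone in K", {
  expect_equal(reduced_score(0L, 5L, hp_ref), 1)
  expect_equal(reduced_score(1L, 5L, hp_ref), 1 / 9, tolerance = 1e-12)
  sc <- reduced_score(0:5, 5L, hp_ref)
  expect_true(all(diff(sc) < 0))
  expect_error(reduced_score(6L, 5L, hp_ref), "K must lie")

  # cross-check against the full model on a 2-gene route with M = R evidence
  rt <- route(c("A", "B"), 1L)
  obs <- sample_observation("s", c(A = 1L, B = -1L), c(A = 1L, B = -1L))
  expect_equal(route_score(rt, obs, hp_ref), reduced_score(1L, 1L, hp_ref),
               tolerance = 1e-12)
})

test_that("hyper-parameter validation enforces the admissible region", {
  expect_error(hyperparams(epsilon = 0.6), "epsilon")
  expect_error(hyperparams(epsilon = 0.3, gamma = 0.2), "gamma")
  expect_error(hyperparams(t = 0), "t must")
  expect_error(hyperparams(alpha = 1), "alpha")
})
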