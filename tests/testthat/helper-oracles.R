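# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path enumeration goes through igraph, route
# scores through exhaustive joint-probability enumeration with the CPTs
# transcribed directly, and Poisson-binomial masses through subset sums.

# all simple paths of length 2..max_len genes from `start`, as sorted
# comma-joined id strings (igraph as the enumeration oracle)
oracle_simple_paths <- function(graph, start, max_len = 12L) {
  g <- pathway_igraph(graph)
  paths <- igraph::all_simple_paths(g, from = start, mode = "out",
                                    cutoff = max_len - 1L)
  ids <- vapply(paths, function(p) paste(names(p), collapse = ","),
                character(1))
  sort(ids[vapply(paths, length, integer(1)) >= 2L])
}

# P(child = +1 | sign, m, r) straight from the activation/inhibition tables
oracle_cpt_plus <- function(sign, m, r, eps, gam) {
  p_act <- if (m == 1 && r == 1) 1 - eps
  else if (m == -1 && r == 1) gam
  else if (m == 1 && r == -1) 1 - gam
  else eps
  if (sign == 1) p_act else 1 - p_act
}

# probability of the evidence by brute-force enumeration over every joint
# assignment of the w expression and w-1 mutation variables
oracle_evidence_prob <- function(signs, r_ev, m_ev, eps, gam) {
  w <- length(signs) + 1L
  vars <- c(rep(list(c(1L, -1L)), w), rep(list(c(1L, -1L)), w - 1L))
  grid <- do.call(expand.grid, vars)
  total <- 0
  for (row in seq_len(nrow(grid))) {
    a <- as.integer(grid[row, ])
    r <- a[1:w]
    m <- a[(w + 1):(2L * w - 1L)]
    if (any(!is.na(r_ev) & r != r_ev)) next
    if (any(!is.na(m_ev) & m != m_ev)) next
    p <- 0.5 * 0.5^(w - 1L)
    for (j in seq_len(w - 1L)) {
      pp <- oracle_cpt_plus(signs[j], m[j], r[j], eps, gam)
      p <- p * if (r[j + 1L] == 1L) pp else 1 - pp
    }
    total <- total + p
  }
  total
}

# full route score by enumeration: evidence probability normalized by the
# probability of the consistent observation with the same availability
# pattern, anchored at the first observed gene
oracle_route_score <- function(rt, obs, hp) {
  w <- length(rt$genes)
  r_ev <- unname(obs$r[rt$genes])
  m_ev <- unname(obs$m[rt$genes[-w]])
  if (is.null(obs$m) || length(obs$m) == 0L) m_ev <- rep(NA_integer_, w - 1L)
  obs_pos <- which(!is.na(r_ev))
  stopifnot(length(obs_pos) >= 2L)
  rdot <- cumprod(c(1L, rt$signs))
  rstar <- as.integer(rdot * r_ev[obs_pos[1L]] * rdot[obs_pos[1L]])
  num <- oracle_evidence_prob(rt$signs, r_ev, m_ev, hp$epsilon, hp$gamma)
  den <- oracle_evidence_prob(rt$signs,
                              ifelse(is.na(r_ev), NA_integer_, rstar),
                              ifelse(is.na(m_ev), NA_integer_, rstar[-w]),
                              hp$epsilon, hp$gamma)
  num / den
}

# Poisson-binomial P(Q = q) by explicit subset enumeration (k small)
oracle_poisson_binomial <- function(probs, q) {
  k <- length(probs)
  total <- 0
  for (mask in 0:(2^k - 1L)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    if (sum(on) != q) next
    total <- total + prod(ifelse(on, probs, 1 - probs))
  }
  total
}

# a random route of w genes with random signs
random_route <- function(w, seed) {
  set.seed(seed)
  route(sprintf("R%02d", sample(99, w)),
        sample(c(1L, -1L), w - 1L, replace = TRUE))
}

# a random pathway graph on <= n nodes (possibly cyclic, no self-loops)
random_small_graph <- function(n, seed, p = 0.35) {
  set.seed(seed)
  genes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(s = genes, t = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- runif(nrow(pairs)) < p
  ed <- pairs[keep, , drop = FALSE]
  if (nrow(ed) == 0L) ed <- pairs[1L, , drop = FALSE]
  ed$sign <- sample(c(1L, -1L), nrow(ed), replace = TRUE)
  pathway_graph(data.frame(source = ed$s, target = ed$t, sign = ed$sign),
                name = sprintf("rand%d", seed), nodes = genes)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
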