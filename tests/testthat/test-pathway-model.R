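test_that("edge-list loading transcribes rows and validates the graph", {
  p <- write_lines_tmp(c("source\ttarget\tsign",
                         "A\tB\tactivation",
                         "B\tC\tinhibition"))
  g <- load_edge_list(p)
  expect_s3_class(g, "pathway_graph")
  expect_equal(g$nodes, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$edges$sign, c(1L, -1L))

  # numeric sign tokens are accepted too, and row order is irrelevant
  p2 <- write_lines_tmp(c("source\ttarget\tsign",
                          "B\tC\t-1",
                          "A\tB\t+1"))
  expect_equal(load_edge_list(p2, name = "x")$edges,
               load_edge_list(p, name = "x")$edges)
})

test_that("edge-list loading rejects malformed input with clear errors", {
  expect_error(
    load_edge_list(write_lines_tmp(c("source\ttarget\tsign",
                                     "A\tA\tactivation"))),
    "self-loop")
  expect_error(
    load_edge_list(write_lines_tmp(c("source\ttarget\tsign",
                                     "A\tB\tactivation",
                                     "A\tB\tinhibition"))),
    "conflicting duplicate")
  expect_error(
    load_edge_list(write_lines_tmp(c("source\ttarget\tsign",
                                     "A\tB\tactivation",
                                     "B\tC\tmaybe"))),
    "unknown sign token 'maybe' at data line 2")
  expect_error(
    load_edge_list(write_lines_tmp(c("from\tto\tsign", "A\tB\tactivation"))),
    "expected header columns")
})

kgml_doc <- function(relations, entries = NULL) {
  if (is.null(entries)) {
    entries <- c('<entry id="1" type="gene" name="hsa:101 hsa:102">',
                 '<graphics name="CCNE1, CCNE"/></entry>',
                 '<entry id="2" type="gene" name="hsa:201"><graphics name="CDK2"/></entry>',
                 '<entry id="3" type="gene" name="hsa:301"><graphics name="RB1"/></entry>')
  }
  write_lines_tmp(c('<?xml version="1.0"?>',
                    '<pathway name="path:test" title="Test pathway">',
                    entries, relations, '</pathway>'),
                  ext = ".xml")
}

test_that("KGML subtype mapping: activation/expression +1, inhibition/repression -1", {
  g <- load_kgml(kgml_doc(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>'))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$sign, 1L)
  expect_equal(g$edges$source, "HSA:101")  # first KEGG id is canonical

  g2 <- load_kgml(kgml_doc(
    c('<relation entry1="2" entry2="3" type="PPrel"><subtype name="inhibition" value="--|"/></relation>',
      '<relation entry1="1" entry2="3" type="GErel"><subtype name="repression" value="--|"/></relation>')))
  expect_equal(sort(g2$edges$sign), c(-1L, -1L))
})

test_that("KGML relations without a signed subtype are skipped and counted", {
  expect_warning(
    g <- load_kgml(kgml_doc(
      '<relation entry1="1" entry2="2" type="PPrel"><subtype name="binding/association" value="---"/></relation>')),
    "no signed relations")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(attr(g, "kgml_report")$n_skipped, 1L)
  # but an explicit include-list can admit extra subtypes
  g3 <- load_kgml(kgml_doc(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="phosphorylation" value="+p"/></relation>'),
    include_subtypes = c(phosphorylation = 1L))
  expect_equal(g3$edges$sign, 1L)
})

test_that("KGML group entries expand to their member genes", {
  entries <- c('<entry id="1" type="gene" name="hsa:101"><graphics name="A"/></entry>',
               '<entry id="2" type="gene" name="hsa:201"><graphics name="B"/></entry>',
               '<entry id="3" type="gene" name="hsa:301"><graphics name="C"/></entry>',
               '<entry id="9" type="group"><component id="1"/><component id="2"/></entry>')
  g <- load_kgml(kgml_doc(
    '<relation entry1="9" entry2="3" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    entries = entries))
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(g$edges$source, c("HSA:101", "HSA:201"))
  expect_equal(unique(g$edges$target), "HSA:301")
})

test_that("route enumeration handles chains, cycles and isolated starts", {
  chain <- pathway_graph(data.frame(source = c("A", "B"),
                                    target = c("B", "C"),
                                    sign = c(1L, -1L)))
  ids <- vapply(enumerate_routes(chain, "A", 3L), route_id, character(1))
  expect_equal(ids, c("A,B", "A,B,C"))
  expect_equal(enumerate_routes(chain, "A", 2L)[[1]]$signs, 1L)

  triangle <- pathway_graph(data.frame(source = c("A", "B", "C"),
                                       target = c("B", "C", "A"),
                                       sign = 1L))
  ids <- vapply(enumerate_routes(triangle, "A", 10L), route_id, character(1))
  expect_equal(ids, c("A,B", "A,B,C"))  # cycle truncated at revisit

  iso <- pathway_graph(data.frame(source = "A", target = "B", sign = 1L),
                       nodes = c("A", "B", "Z"))
  expect_length(enumerate_routes(iso, "Z", 5L), 0L)
  expect_error(enumerate_routes(iso, "Q", 5L), "not in pathway")
})

test_that("route enumeration matches brute-force simple-path enumeration", {
  for (seed in 1:15) {
    g <- random_small_graph(n = sample(4:8, 1), seed = seed)
    for (start in g$nodes) {
      got <- sort(vapply(enumerate_routes(g, start, 8L), route_id,
                         character(1)))
      expect_equal(got, oracle_simple_paths(g, start, 8L),
                   info = sprintf("seed %d start %s", seed, start))
    }
  }
})

test_that("enumeration is invariant under edge-order permutation", {
  g <- random_small_graph(6, seed = 99)
  set.seed(7)
  perm <- sample(nrow(g$edges))
  g2 <- pathway_graph(g$edges[perm, ], name = g$name, nodes = g$nodes)
  ids1 <- sort(vapply(enumerate_all_routes(g, 8L), route_id, character(1)))
  ids2 <- sort(vapply(enumerate_all_routes(g2, 8L), route_id, character(1)))
  expect_equal(ids1, ids2)
})

test_that("route counts in a DAG match the dynamic-programming recurrence", {
  set.seed(11)
  # random DAG on 7 nodes (edges only forward in node order => acyclic)
  genes <- LETTERS[1:7]
  pairs <- expand.grid(i = 1:7, j = 1:7)
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs <- pairs[runif(nrow(pairs)) < 0.4, ]
  g <- pathway_graph(data.frame(source = genes[pairs$i],
                                target = genes[pairs$j], sign = 1L),
                     nodes = genes)
  A <- matrix(0L, 7, 7, dimnames = list(genes, genes))
  A[cbind(g$edges$source, g$edges$target)] <- 1L
  # in a DAG every walk is simple: path count = sum of powers of A
  Ak <- A
  counts <- rowSums(A)
  for (len in 2:6) {
    Ak <- Ak %*% A
    counts <- counts + rowSums(Ak)
  }
  for (v in genes) {
    expect_length(enumerate_routes(g, v, max_len = 7L), counts[v])
  }
})

test_that("route constructors validate and graphs round-trip through files", {
  expect_error(route("A", integer()), "at least two genes")
  expect_error(route(c("A", "A"), 1L), "pairwise distinct")
  expect_error(route(c("A", "B"), 2L), "signs must be")

  g <- random_small_graph(6, seed = 3)
  rt <- enumerate_all_routes(g, 5L)[[1]]
  expect_equal(route_from_genes(g, rt$genes)$signs, rt$signs)

  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(g, tsv)
  expect_equal(load_edge_list(tsv, name = g$name)$edges, g$edges)

  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  g2 <- load_graphml(gml, name = g$name)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$nodes, g$nodes)
})
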