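pairs3 <- data.frame(drug_id = c("d1", "d2", "d3"), target_id = "T")
no_edges <- data.frame(target_a = character(0), target_b = character(0),
                       confidence = numeric(0))

test_that("graph construction filters and deduplicates", {
  edges <- data.frame(target_a = c("A", "B"), target_b = c("B", "C"),
                      confidence = c(0.71, 0.5))
  g <- build_drug_target_graph(pairs3, edges, hits = c("d1", "d2", "d3"))
  expect_equal(nrow(g$target_edges), 1)
  expect_equal(g$target_edges$confidence, 0.71)
  # cutoff is inclusive
  g2 <- build_drug_target_graph(pairs3, data.frame(
    target_a = "A", target_b = "B", confidence = 0.7), c("d1"))
  expect_equal(nrow(g2$target_edges), 1)
  # cutoff 1.0 with all confidences below it empties the edge set
  g3 <- build_drug_target_graph(pairs3, edges, c("d1"),
                                confidence_cutoff = 1.0)
  expect_equal(nrow(g3$target_edges), 0)
  # duplicate undirected edge stored once, keeping max confidence
  dup <- data.frame(target_a = c("A", "B"), target_b = c("B", "A"),
                    confidence = c(0.8, 0.9))
  g4 <- build_drug_target_graph(pairs3, dup, c("d1"))
  expect_equal(nrow(g4$target_edges), 1)
  expect_equal(g4$target_edges$confidence, 0.9)
  # self-edges dropped, bad confidences rejected, non-hit pairs dropped
  self <- data.frame(target_a = "A", target_b = "A", confidence = 0.9)
  expect_equal(nrow(build_drug_target_graph(pairs3, self,
                                            c("d1"))$target_edges), 0)
  expect_error(build_drug_target_graph(pairs3, data.frame(
    target_a = "A", target_b = "B", confidence = 1.2), c("d1")),
    "\\[0, 1\\]")
  g5 <- build_drug_target_graph(pairs3, edges, hits = c("d1", "d9"))
  expect_equal(g5$pairs$drug_id, "d1")
})

test_that("recurrence counts distinct drugs per target", {
  g <- build_drug_target_graph(pairs3, no_edges,
                               hits = c("d1", "d2", "d3"))
  expect_equal(target_recurrence(g)[["T"]], 3)
  # unique targets -> all counts 1
  uniq <- data.frame(drug_id = c("d1", "d2"), target_id = c("T1", "T2"))
  gu <- build_drug_target_graph(uniq, g$target_edges, c("d1", "d2"))
  expect_true(all(target_recurrence(gu) == 1))
  # a duplicated pair still counts its drug once
  dupp <- rbind(pairs3, pairs3[1, ])
  gd <- build_drug_target_graph(dupp, g$target_edges, c("d1", "d2", "d3"))
  expect_equal(target_recurrence(gd)[["T"]], 3)
})

test_that("hit selection by construction and at a stricter cutoff", {
  tabs <- simulate_drug_target_tables(network_params(
    12, recurrent_target_spec = c(T1 = 3), unknown_fraction = 0.25,
    edge_density = 0.1, seed = 21))
  g <- build_drug_target_graph(tabs$pairs, tabs$edges, tabs$hit_ids)
  rep3 <- select_hits(g, recurrence_cutoff = 3)
  expect_true("T1" %in% rep3$recurrent_targets)
  t1_drugs <- unique(g$pairs$drug_id[g$pairs$target_id == "T1"])
  expect_true(all(t1_drugs %in% rep3$favorite_hits))
  expect_setequal(rep3$unknown_hits, tabs$unknown_ids)
  # disjointness and coverage of the hit partition
  neither <- setdiff(tabs$hit_ids,
                     union(rep3$favorite_hits, rep3$unknown_hits))
  expect_length(intersect(rep3$favorite_hits, rep3$unknown_hits), 0)
  expect_setequal(union(union(rep3$favorite_hits, rep3$unknown_hits),
                        neither), tabs$hit_ids)
  # raising the cutoff above the designed multiplicity clears favorites
  rep4 <- select_hits(g, recurrence_cutoff = 4)
  expect_false("T1" %in% rep4$recurrent_targets)
  # drugs with no pairs stay unknown regardless of cutoff
  expect_setequal(rep4$unknown_hits, tabs$unknown_ids)
})

test_that("cutoffs act monotonically", {
  tabs <- simulate_drug_target_tables(network_params(
    15, n_targets = 10, recurrent_target_spec = c(T1 = 4, T2 = 3),
    edge_density = 0.3, seed = 33))
  n_edges_prev <- Inf
  n_fav_prev <- Inf
  for (cc in c(0, 0.3, 0.6, 0.9)) {
    g <- build_drug_target_graph(tabs$pairs, tabs$edges, tabs$hit_ids, cc)
    expect_lte(nrow(g$target_edges), n_edges_prev)
    n_edges_prev <- nrow(g$target_edges)
  }
  g <- build_drug_target_graph(tabs$pairs, tabs$edges, tabs$hit_ids)
  for (rc in 1:5) {
    rep <- select_hits(g, recurrence_cutoff = rc)
    expect_lte(length(rep$favorite_hits), n_fav_prev)
    n_fav_prev <- length(rep$favorite_hits)
  }
})

test_that("components agree with a union-find oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:20, 1)
    nodes <- sprintf("T%02d", seq_len(n))
    m <- sample(0:25, 1)
    edges <- data.frame(
      target_a = sample(nodes, m, replace = TRUE),
      target_b = sample(nodes, m, replace = TRUE),
      confidence = 1)
    edges <- edges[edges$target_a != edges$target_b, , drop = FALSE]
    pairs <- data.frame(drug_id = "d1", target_id = nodes)
    g <- build_drug_target_graph(pairs, edges, "d1")
    comp <- select_hits(g, recurrence_cutoff = 99)$components
    oracle <- oracle_components(nodes, g$target_edges$target_a,
                                g$target_edges$target_b)
    # same partition up to relabeling
    expect_equal(length(unique(comp[nodes])), length(unique(oracle)))
    same_pkg <- outer(comp[nodes], comp[nodes], "==")
    same_ora <- outer(oracle, oracle, "==")
    expect_true(all(same_pkg == same_ora))
  }
})

test_that("exported tables reconstruct the same report", {
  tabs <- simulate_drug_target_tables(network_params(
    10, recurrent_target_spec = c(T1 = 3), edge_density = 0.4, seed = 2))
  g <- build_drug_target_graph(tabs$pairs, tabs$edges, tabs$hit_ids)
  rep <- select_hits(g)
  dir <- withr::local_tempdir()
  export_network(g, rep, dir)
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(nodes),
               length(unique(g$pairs$drug_id)) +
                 length(unique(c(g$pairs$target_id,
                                 g$target_edges$target_a,
                                 g$target_edges$target_b))))
  # rebuild from the exported edge table
  dt <- edges[edges$kind == "drug_target", ]
  tt <- edges[edges$kind == "target_target", ]
  g2 <- build_drug_target_graph(
    data.frame(drug_id = dt$from, target_id = dt$to),
    data.frame(target_a = tt$from, target_b = tt$to,
               confidence = tt$confidence),
    tabs$hit_ids)
  rep2 <- select_hits(g2)
  expect_equal(rep2$recurrence[order(names(rep2$recurrence))],
               rep$recurrence[order(names(rep$recurrence))])
  expect_equal(rep2$favorite_hits, rep$favorite_hits)

  # empty graph exports header-only tables
  ge <- build_drug_target_graph(pairs3[0, ], no_edges, character(0))
  dir2 <- withr::local_tempdir()
  export_network(ge, select_hits(ge), dir2)
  expect_length(readLines(file.path(dir2, "nodes.tsv")), 1)
  expect_length(readLines(file.path(dir2, "edges.tsv")), 1)
})
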