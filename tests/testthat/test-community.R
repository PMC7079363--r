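test_that("edge betweenness matches exhaustive path enumeration", {
  # structured small graphs plus random sparse graphs, all <= 8 nodes
  graphs <- list(
    edges_df(c("A", "B", "C"), c("B", "C", "D")),             # path
    edges_df(rep("H", 5), c("L1", "L2", "L3", "L4", "L5")),   # star
    edges_df(c("A", "B", "C", "D"), c("B", "C", "D", "A")),   # cycle
    edges_df(c("A", "A", "B", "D", "D", "E", "C"),            # 2 triangles
             c("B", "C", "C", "E", "F", "F", "D"))            # + bridge
  )
  set.seed(161)
  for (i in 1:6) {
    nodes <- sprintf("N%d", 1:8)
    a <- sample(nodes, 12, replace = TRUE)
    b <- sample(nodes, 12, replace = TRUE)
    keep <- a != b
    graphs <- c(graphs, list(unique(edges_df(pmin(a, b)[keep],
                                             pmax(a, b)[keep]))))
  }
  for (g in graphs) {
    net <- as_weighted_network(g)
    expect_equal(edge_betweenness(net), brute_edge_betweenness(net$edges),
                 tolerance = 1e-12)
  }
})

test_that("two cliques joined by a bridge split at the bridge", {
  cl1 <- sprintf("A%d", 1:5)
  cl2 <- sprintf("B%d", 1:5)
  edges <- rbind(clique_edges(cl1), clique_edges(cl2),
                 edges_df("A1", "B1"))
  net <- as_weighted_network(edges)
  ms <- girvan_newman(net)
  expect_identical(ms$n_communities, 2L)
  expect_length(unique(ms$membership[cl1]), 1L)
  expect_length(unique(ms$membership[cl2]), 1L)
  expect_false(ms$membership[["A1"]] == ms$membership[["B1"]])
  # modularity of the two-clique split: 2 * (10/21 - (21/42)^2)
  expect_equal(ms$modularity, 2 * (10 / 21 - 0.25), tolerance = 1e-12)

  # the bridge carries maximal betweenness
  eb <- edge_betweenness(net)
  bridge <- which(net$edges$node_a == "A1" & net$edges$node_b == "B1")
  expect_identical(which.max(eb), bridge)
})

test_that("indivisible graphs keep the trivial partition with Q = 0", {
  k5 <- as_weighted_network(clique_edges(sprintf("K%d", 1:5)))
  ms <- girvan_newman(k5)
  expect_identical(ms$n_communities, 1L)
  expect_equal(ms$modularity, 0)
})

test_that("disconnected components are partitioned independently", {
  edges <- rbind(clique_edges(sprintf("A%d", 1:4)),
                 clique_edges(sprintf("B%d", 1:4)))
  ms <- girvan_newman(as_weighted_network(edges))
  expect_identical(ms$n_communities, 2L)
  expect_length(unique(ms$membership[sprintf("A%d", 1:4)]), 1L)
})

test_that("community detection is deterministic and matches igraph", {
  skip_if_not_installed("igraph")
  set.seed(171)
  # planted partition graph: 3 groups of 12, dense within, sparse between
  nodes <- sprintf("N%02d", 1:36)
  grp <- rep(1:3, each = 12)
  prs <- t(combn(seq_along(nodes), 2))
  p_edge <- ifelse(grp[prs[, 1]] == grp[prs[, 2]], 0.8, 0.06)
  sel <- runif(nrow(prs)) < p_edge
  edges <- edges_df(nodes[prs[sel, 1]], nodes[prs[sel, 2]])
  net <- as_weighted_network(edges)

  ms1 <- girvan_newman(net)
  ms2 <- girvan_newman(net)
  expect_identical(ms1, ms2)

  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, 1:2]),
                                   directed = FALSE)
  cm <- igraph::cluster_edge_betweenness(g, weights = NULL)
  common <- intersect(names(ms1$membership), names(igraph::membership(cm)))
  expect_equal(mclust::adjustedRandIndex(
    ms1$membership[common], igraph::membership(cm)[common]), 1)
  expect_equal(ms1$modularity, igraph::modularity(cm), tolerance = 1e-10)
})

test_that("module filtering orders by size and applies the cutoff", {
  edges <- rbind(clique_edges(sprintf("A%d", 1:20)),
                 clique_edges(sprintf("B%d", 1:15)),
                 clique_edges(sprintf("C%d", 1:5)))
  ms <- girvan_newman(as_weighted_network(edges))
  mods <- filter_modules(ms, min_size = 10)
  expect_identical(nrow(mods), 2L)
  expect_identical(mods$size, c(20L, 15L))

  # all singleton communities -> nothing passes
  pairs <- as_weighted_network(edges_df(c("X1", "Y1"), c("X2", "Y2")))
  ms2 <- girvan_newman(pairs)
  expect_identical(nrow(filter_modules(ms2, min_size = 10)), 0L)
})

test_that("the reversal test matches a textbook paired t computation", {
  prot <- sprintf("P%d", 1:5)
  d <- c(0.5, 0.6, 0.4, 0.5, 0.5)
  lfc_a <- setNames(d, prot)
  lfc_b <- setNames(rep(0, 5), prot)
  rt <- module_reversal_test(prot, lfc_a, lfc_b)
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(rt$t, t_oracle, tolerance = 1e-10)
  expect_equal(rt$p_value, p_oracle, tolerance = 1e-10)
  expect_true(rt$flag)

  # identical fold changes: p = 1, not flagged
  rt0 <- module_reversal_test(prot, lfc_a, lfc_a)
  expect_equal(rt0$p_value, 1)
  expect_false(rt0$flag)

  # constant nonzero differences are degenerate for the paired test
  expect_error(module_reversal_test(prot, lfc_a, lfc_a - 0.3), "paired")
  rt_w <- module_reversal_test(prot, lfc_a, lfc_a - 0.3, paired = FALSE)
  expect_true(is.finite(rt_w$p_value))
})

test_that("a strong reversal is flagged consistently across seeded runs", {
  hits <- 0L
  n_runs <- 200
  set.seed(181)
  prot <- sprintf("P%d", 1:15)
  for (r in seq_len(n_runs)) {
    lfc_a <- setNames(rnorm(15, 1, 0.1), prot)
    lfc_b <- setNames(rnorm(15, 0, 0.1), prot)
    if (module_reversal_test(prot, lfc_a, lfc_b)$flag) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.99)
})

test_that("module enrichment reports the top qualifying set or none", {
  members <- sprintf("G%d", 1:12)
  universe <- sprintf("G%d", 1:100)
  edges <- clique_edges(members)
  ms <- girvan_newman(as_weighted_network(edges))
  collection <- list(EXACT = members, OTHER = sprintf("G%d", 50:60))
  me <- module_enrichment(ms, collection, universe, min_size = 10)
  expect_identical(nrow(me), 1L)
  expect_identical(me$top_set, "EXACT")
  expect_equal(me$neg_log10_p, -log10(me$p_value))

  disjoint <- list(OTHER = sprintf("G%d", 50:60))
  me2 <- module_enrichment(ms, disjoint, universe, min_size = 10)
  expect_identical(me2$top_set, "none")
})
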