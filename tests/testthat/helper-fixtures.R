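# shared fixture builders and independent oracles

# tiny abundance matrix: p proteins x (3 conditions x reps), values supplied
# or drawn N(mean0, sd0) on the raw scale
make_matrix <- function(values, conditions = rep(c("O19", "O1", "O1_CyA"),
                                                 each = 3),
                        replicates = rep(1:3, times = 3),
                        proteins = NULL) {
  if (is.null(proteins)) proteins <- sprintf("P%d", seq_len(nrow(values)))
  samples <- paste0(conditions, "_r", replicates)
  dimnames(values) <- list(proteins, samples)
  meta <- data.frame(sample_id = samples, condition = conditions,
                     replicate = replicates, stringsAsFactors = FALSE)
  abundance_matrix(values, meta, scale = "raw")
}

# log2-scale matrix straight from a value matrix (bypasses positivity checks)
make_log2_matrix <- function(values, ...) {
  m <- make_matrix(2^values, ...)
  log2_transform(m)
}

# independent edge-betweenness oracle: exhaustive shortest-path enumeration
# (all shortest paths between every unordered node pair, each path weighted
# 1/#paths, summed per edge). Only for tiny graphs.
brute_edge_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  adj <- lapply(setNames(nm = nodes), function(v) {
    c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
  })
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  score <- setNames(numeric(nrow(edges)), ekey(edges$node_a, edges$node_b))
  all_shortest_paths <- function(s, t) {
    # BFS distances from s, then DFS back from t over steepest predecessors
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
    if (dist[t] == Inf) return(list())
    expand <- function(v) {
      if (v == s) return(list(s))
      preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      out <- list()
      for (p in unique(preds))
        for (pp in expand(p)) out <- c(out, list(c(pp, v)))
      out
    }
    expand(t)
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- all_shortest_paths(nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      ks <- ekey(p[-length(p)], p[-1])
      score[ks] <- score[ks] + 1 / length(paths)
    }
  }
  unname(score[ekey(edges$node_a, edges$node_b)])
}

# canonical edge data frame from a 2-column matrix of node names
edges_df <- function(a, b, weight = 0.9, zscore = 2) {
  data.frame(node_a = a, node_b = b, weight = weight, zscore = zscore,
             stringsAsFactors = FALSE)
}

# clique edge list on the given node names
clique_edges <- function(nodes) {
  prs <- t(combn(nodes, 2))
  edges_df(prs[, 1], prs[, 2])
}
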