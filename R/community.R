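#' Edge betweenness of a network
#'
#' Betweenness of every edge (number of shortest paths between unordered
#' node pairs passing through the edge, with path counts split across ties)
#' on the unweighted graph.
#'
#' @param network A `WeightedNetwork`.
#' @return Numeric vector, one value per row of `network$edges`.
#' @export
edge_betweenness <- function(network) {
  stopifnot(inherits(network, "WeightedNetwork"))
  if (!nrow(network$edges)) return(numeric())
  idx <- edge_index_matrix(network)
  as.numeric(cpp_edge_betweenness(idx$edges, idx$n))
}

# map canonical edge data frame to 0-based integer matrix + node vector
edge_index_matrix <- function(network) {
  nodes <- network$nodes
  e <- cbind(match(network$edges$node_a, nodes),
             match(network$edges$node_b, nodes)) - 1L
  storage.mode(e) <- "integer"
  list(edges = e, n = length(nodes), nodes = nodes)
}

#' Girvan-Newman community detection with a modularity cut
#'
#' Iteratively removes the edge with maximal betweenness (recomputed after
#' every removal; ties broken by canonical edge order) and selects, across
#' the removal sequence, the connected-component partition maximizing
#' Newman-Girvan modularity `Q = sum_c (e_c/m - (d_c/2m)^2)` on the
#' original unweighted graph. Deterministic; disconnected inputs are
#' partitioned independently per component.
#'
#' @param network A non-empty `WeightedNetwork`.
#' @return A `ModuleSet`: list with `membership` (named integer vector,
#'   module ids assigned by decreasing module size, starting at 1),
#'   `modularity` (Q of the selected partition), `n_communities`,
#'   `sizes` (named integer vector).
#' @export
girvan_newman <- function(network) {
  stopifnot(inherits(network, "WeightedNetwork"))
  if (!length(network$nodes)) stop("empty network")
  idx <- edge_index_matrix(network)
  res <- cpp_girvan_newman(idx$edges, idx$n)
  memb0 <- res$membership # 0-based, arbitrary order
  # reassign ids by decreasing size (ties: first appearance in node order)
  tab <- sort(table(memb0), decreasing = TRUE)
  remap <- setNames(seq_along(tab), names(tab))
  membership <- setNames(as.integer(remap[as.character(memb0)]), idx$nodes)
  sizes <- sort(table(membership), decreasing = TRUE)
  structure(list(
    membership = membership,
    modularity = res$modularity,
    n_communities = res$n_communities,
    sizes = setNames(as.integer(sizes), names(sizes))
  ), class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$modularity))
  invisible(x)
}

#' Filter modules by size
#'
#' @param modules A `ModuleSet` from [girvan_newman()].
#' @param min_size Minimum module size (default 10).
#' @return Data frame with columns `module_id`, `size`, `members`
#'   (comma-separated), ordered by size descending then module id.
#' @export
filter_modules <- function(modules, min_size = 10) {
  stopifnot(inherits(modules, "ModuleSet"))
  keep <- modules$sizes[modules$sizes >= min_size]
  if (!length(keep))
    return(data.frame(module_id = integer(), size = integer(),
                      members = character(), stringsAsFactors = FALSE))
  ids <- as.integer(names(keep))
  ord <- order(-as.integer(keep), ids)
  ids <- ids[ord]
  data.frame(
    module_id = ids,
    size = as.integer(keep[ord]),
    members = vapply(ids, function(i) {
      paste(sort(names(modules$membership)[modules$membership == i]),
            collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

# members of one module as a character vector
module_members <- function(modules, module_id) {
  sort(names(modules$membership)[modules$membership == module_id])
}

#' Module fold-change reversal test
#'
#' Tests whether a module's distribution of per-protein log2 fold changes
#' differs between the normoxia-vs-hypoxia contrast and the
#' normoxia-vs-hypoxia+drug contrast: a two-tailed PAIRED t-test across the
#' module's proteins on `lfc_A - lfc_B` (the same proteins appear in both
#' contrasts). A significant difference with the drug contrast near zero is
#' the signature of a treatment-restored module. An unpaired Welch
#' alternative is available via `paired = FALSE`.
#'
#' @param members Character vector of module member proteins (size >= 2).
#' @param lfc_A Named per-protein median log2FC for contrast O19_vs_O1
#'   (see [replicate_wise_lfc()]).
#' @param lfc_B Same for contrast O19_vs_O1CyA.
#' @param alpha Flag threshold (default 0.05).
#' @param paired Use the paired t-test (default `TRUE`).
#' @return List with `p_value`, `t`, `flag`, `mean_diff`, `n`.
#' @export
module_reversal_test <- function(members, lfc_A, lfc_B, alpha = 0.05,
                                 paired = TRUE) {
  members <- intersect(members, intersect(names(lfc_A), names(lfc_B)))
  if (length(members) < 2)
    stop("reversal test needs >= 2 module members with fold changes")
  a <- lfc_A[members]
  b <- lfc_B[members]
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      if (all(d == 0))
        return(list(p_value = 1, t = 0, flag = FALSE, mean_diff = 0,
                    n = length(members)))
      stop("zero variance of paired differences with nonzero mean; ",
           "use paired = FALSE")
    }
    tt <- t.test(a, b, paired = TRUE)
  } else {
    tt <- t.test(a, b, paired = FALSE)
  }
  p <- tt$p.value
  list(p_value = p, t = unname(tt$statistic), flag = p <= alpha,
       mean_diff = mean(a) - mean(b), n = length(members))
}

#' Per-module top enriched pathway
#'
#' For each module (of size >= `min_size`), reports the smallest-p gene set
#' at `p <= alpha` via the hypergeometric test, or `"none"`.
#'
#' @param modules A `ModuleSet`.
#' @param collection A `GeneSetCollection`.
#' @param universe Background gene universe.
#' @param min_size Minimum module size (default 10).
#' @param alpha Enrichment threshold on the raw hypergeometric p
#'   (default 0.05).
#' @param ... Passed to [hypergeometric_enrich()].
#' @return Data frame: `module_id`, `size`, `top_set`, `p_value`,
#'   `neg_log10_p` (NA when no set qualifies).
#' @export
module_enrichment <- function(modules, collection, universe, min_size = 10,
                              alpha = 0.05, ...) {
  mods <- filter_modules(modules, min_size)
  rows <- lapply(seq_len(nrow(mods)), function(i) {
    members <- strsplit(mods$members[i], ",", fixed = TRUE)[[1]]
    res <- suppressWarnings(
      hypergeometric_enrich(members, collection, universe, ...))
    res <- res[res$p_value <= alpha, , drop = FALSE]
    if (nrow(res)) {
      data.frame(module_id = mods$module_id[i], size = mods$size[i],
                 top_set = res$set_name[1], p_value = res$p_value[1],
                 neg_log10_p = -log10(res$p_value[1]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(module_id = mods$module_id[i], size = mods$size[i],
                 top_set = "none", p_value = NA_real_,
                 neg_log10_p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(module_id = integer(), size = integer(),
                      top_set = character(), p_value = numeric(),
                      neg_log10_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
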