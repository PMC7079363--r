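#' Build the knowledge-based network
#'
#' Restricts a curated interaction edge table (gene pairs with a confidence
#' score in [0,1]) to edges whose endpoints both belong to the supplied
#' pathway gene list and whose score reaches `min_score`. Identifiers are
#' uppercased; edges are canonicalized. The interaction table is an input
#' file — nothing is queried online.
#'
#' @param edge_table Data frame with two gene columns and a score column
#'   (names `gene_a`, `gene_b`, `score`; the first three columns are used
#'   if those names are absent).
#' @param pathway_genes Character vector of pathway member genes.
#' @param min_score Minimum confidence score (default 0.4, the conventional
#'   medium-confidence cutoff).
#' @return A `KnowledgeNetwork`: list with `nodes`, `edges`
#'   (`node_a`, `node_b`, `score`), `pathway_genes`, `min_score`.
#' @export
build_knowledge_network <- function(edge_table, pathway_genes,
                                    min_score = 0.4) {
  if (!length(pathway_genes)) stop("empty pathway gene list")
  if (!all(c("gene_a", "gene_b", "score") %in% names(edge_table))) {
    if (ncol(edge_table) < 3)
      stop("edge table needs two gene columns and a score column")
    names(edge_table)[1:3] <- c("gene_a", "gene_b", "score")
  }
  genes <- unique(toupper(pathway_genes))
  df <- data.frame(node_a = toupper(edge_table$gene_a),
                   node_b = toupper(edge_table$gene_b),
                   weight = as.numeric(edge_table$score),
                   zscore = NA_real_, stringsAsFactors = FALSE)
  if (any(df$weight < 0 | df$weight > 1, na.rm = TRUE))
    stop("confidence scores must lie in [0, 1]")
  df <- df[df$node_a %in% genes & df$node_b %in% genes &
             !is.na(df$weight) & df$weight >= min_score, , drop = FALSE]
  df <- suppressWarnings(canonicalize_edges(df))
  if (!nrow(df)) warning("no edges left after pathway/score restriction")
  structure(list(
    nodes = sort(unique(c(df$node_a, df$node_b))),
    edges = data.frame(node_a = df$node_a, node_b = df$node_b,
                       score = df$weight, stringsAsFactors = FALSE),
    pathway_genes = genes,
    min_score = min_score
  ), class = "KnowledgeNetwork")
}

#' Nodes shared by two networks
#'
#' Intersection of the node sets of a co-expression network and a
#' knowledge-based network (or any two objects carrying `$nodes`), after
#' uppercasing both sides.
#'
#' @param net_a,net_b Networks (`WeightedNetwork`, `KnowledgeNetwork`, or
#'   character vectors of node ids).
#' @return Sorted character vector of shared node ids.
#' @export
overlap_nodes <- function(net_a, net_b) {
  nodes <- function(x) toupper(if (is.character(x)) x else x$nodes)
  sort(intersect(nodes(net_a), nodes(net_b)))
}

#' Degree-ranked hub nodes
#'
#' Node degrees of a network, the top hubs (ties broken alphabetically),
#' the degree histogram and the median degree.
#'
#' @param net A `WeightedNetwork` or `KnowledgeNetwork`.
#' @param top_n Number of hubs to report (default 20; truncated to the node
#'   count).
#' @return List with `hubs` (data frame `node`, `degree`), `degrees`
#'   (named vector over all nodes), `histogram` (data frame `degree`,
#'   `count`), `median_degree`.
#' @export
degree_ranking <- function(net, top_n = 20) {
  edges <- net$edges
  if (!length(net$nodes)) stop("empty network")
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = net$nodes))
  deg <- setNames(as.integer(deg), names(deg))
  ord <- order(-deg, names(deg))
  top <- head(ord, min(top_n, length(deg)))
  hist_tab <- table(deg)
  list(
    hubs = data.frame(node = names(deg)[top], degree = unname(deg[top]),
                      stringsAsFactors = FALSE),
    degrees = deg,
    histogram = data.frame(degree = as.integer(names(hist_tab)),
                           count = as.integer(hist_tab)),
    median_degree = median(deg)
  )
}
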