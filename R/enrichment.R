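#' Hypergeometric over-representation test
#'
#' For each gene set S in the collection, tests whether the query is
#' enriched for S members within a finite universe: with N = |universe|,
#' K = |S intersect universe|, n = |query| and k = |S intersect query|, the
#' p-value is the inclusive upper tail P(X >= k) for
#' X ~ Hypergeometric(N, K, n) — the one-sided Fisher exact convention.
#' Query members outside the universe are dropped with a warning. Sets are
#' size-filtered within the universe (default 3..500) before testing;
#' Benjamini-Hochberg adjustment is applied across all tested sets.
#'
#' @param query Character vector of gene/protein symbols (uppercased
#'   internally).
#' @param collection A `GeneSetCollection` from [read_gmt()] or a named list
#'   of character vectors.
#' @param universe Character vector: the background population.
#' @param min_set_size,max_set_size Size guard rails applied to
#'   `|S intersect universe|` (defaults 3 and 500).
#' @return Data frame sorted by p-value with columns `set_name`, `k`, `n`,
#'   `K`, `N`, `p_value`, `adj_p`, `overlap` (comma-separated members).
#' @export
hypergeometric_enrich <- function(query, collection, universe,
                                  min_set_size = 3, max_set_size = 500) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query member(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  empty <- data.frame(set_name = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      adj_p = numeric(), overlap = character(),
                      stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query after universe intersection")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    S <- intersect(toupper(collection[[nm]]), universe)
    K <- length(S)
    if (K < max(min_set_size, 1) || K > max_set_size) return(NULL)
    hits <- intersect(S, query)
    k <- length(hits)
    # inclusive upper tail P(X >= k); k = 0 gives p = 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               p_value = min(p, 1),
               overlap = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$adj_p <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_name),
             c("set_name", "k", "n", "K", "N", "p_value", "adj_p", "overlap")]
  rownames(res) <- NULL
  res
}

#' Enrichment of differential proteins
#'
#' Convenience wrapper of [hypergeometric_enrich()] for a differential
#' protein set. By default the universe is the quantified proteins
#' intersected with the union of collection members (annotated-only
#' background, the usual over-representation convention);
#' `annotated_only = FALSE` keeps every quantified protein.
#'
#' @param de_set Character vector of differential protein/gene symbols.
#' @param collection A `GeneSetCollection`.
#' @param quantified Character vector: all quantified proteins (post
#'   low-abundance filter).
#' @param annotated_only Restrict the universe to annotated genes
#'   (default `TRUE`).
#' @param path Optional path; when given, the result table is written as TSV.
#' @param ... Passed to [hypergeometric_enrich()].
#' @return The enrichment data frame.
#' @export
enrich_de_proteins <- function(de_set, collection, quantified,
                               annotated_only = TRUE, path = NULL, ...) {
  universe <- unique(toupper(quantified))
  if (annotated_only) {
    annotated <- unique(toupper(unlist(collection, use.names = FALSE)))
    universe <- intersect(universe, annotated)
  }
  res <- hypergeometric_enrich(de_set, collection, universe, ...)
  if (!is.null(path))
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
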