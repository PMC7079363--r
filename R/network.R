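#' All-pairs absolute Pearson correlation
#'
#' Edge weights of the co-expression network: `w(i,j) = |cor(x_i, x_j)|`
#' across samples, for every protein pair. The diagonal is set to `NA`.
#'
#' @param mat An [abundance_matrix()] on the log2 scale with >= 3 samples
#'   and no constant protein (the CV filter guarantees this).
#' @return Symmetric proteins x proteins matrix of absolute correlations.
#' @export
pairwise_abs_pearson <- function(mat) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "log2") stop("correlations are computed on log2 values")
  if (ncol(mat$values) < 3) stop("need >= 3 samples for correlations")
  sds <- apply(mat$values, 1, sd)
  if (any(sds == 0))
    stop("constant protein(s) reached the correlation stage: ",
         paste(head(rownames(mat$values)[sds == 0], 5), collapse = ", "))
  w <- abs(cor(t(mat$values)))
  diag(w) <- NA_real_
  w
}

#' Per-edge permutation z-scores
#'
#' Null-calibrates every pairwise correlation by permutation of sample
#' labels: in each of `n_perm` iterations every protein's values are
#' independently permuted across samples (breaking all inter-protein
#' association while preserving each protein's marginal distribution), and
#' all pairwise absolute correlations are recomputed. The z-score of an edge
#' is `(w_obs - mean_perm) / sd_perm` with the sample (n-1) standard
#' deviation across permutations. A single shared permutation of the columns
#' would leave every correlation unchanged, so the per-row scheme is the
#' operative reading of label permutation.
#'
#' Pairs whose permutation sd is zero get `z = Inf` when the observed weight
#' exceeds the permutation mean and `z = 0` otherwise, with a warning.
#'
#' @param mat An [abundance_matrix()] on the log2 scale.
#' @param n_perm Number of permutations (default 50).
#' @param seed Mandatory integer seed; permutations are deterministic
#'   given it.
#' @return Symmetric matrix of z-scores (diagonal `NA`).
#' @export
permutation_zscores <- function(mat, n_perm = 50, seed) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (n_perm < 2) stop("need n_perm >= 2")
  if (mat$scale != "log2") stop("correlations are computed on log2 values")
  x <- mat$values
  p <- nrow(x)
  n <- ncol(x)
  w_obs <- abs(cor(t(x)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s1 <- matrix(0, p, p)
  s2 <- matrix(0, p, p)
  for (b in seq_len(n_perm)) {
    perm <- x
    for (i in seq_len(p)) perm[i, ] <- perm[i, sample.int(n)]
    wp <- abs(cor(t(perm)))
    s1 <- s1 + wp
    s2 <- s2 + wp * wp
  }
  m <- s1 / n_perm
  v <- (s2 - n_perm * m * m) / (n_perm - 1)
  v[v < 0] <- 0
  sdp <- sqrt(v)
  z <- (w_obs - m) / sdp
  degen <- sdp == 0
  diag(degen) <- FALSE
  if (any(degen)) {
    warning(sum(degen) / 2, " pair(s) with zero permutation sd")
    z[degen] <- ifelse(w_obs[degen] > m[degen], Inf, 0)
  }
  dimnames(z) <- dimnames(w_obs)
  diag(z) <- NA_real_
  z
}

# save/restore the global RNG state so seeded internals do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Dual-threshold the correlation network
#'
#' An edge is retained iff its permutation z-score satisfies
#' `|z| >= z_min` AND its weight exceeds `w_min` strictly (weights <= w_min
#' are removed). Nodes are the endpoints of retained edges: proteins left
#' isolated by the thresholding are dropped from the network.
#'
#' @param weights Symmetric weight matrix from [pairwise_abs_pearson()].
#' @param zscores Symmetric z matrix from [permutation_zscores()] over the
#'   same proteins.
#' @param z_min Minimum absolute z-score (default 1.5).
#' @param w_min Strict lower bound on the weight (default 0.5).
#' @param provenance Optional list (n_perm, seed, ...) recorded on the
#'   network.
#' @return A `WeightedNetwork`: list with `nodes`, `edges` (canonical data
#'   frame `node_a`, `node_b`, `weight`, `zscore`) and `provenance`
#'   (thresholds merged with the supplied list).
#' @export
threshold_network <- function(weights, zscores, z_min = 1.5, w_min = 0.5,
                              provenance = list()) {
  if (!identical(dim(weights), dim(zscores)))
    stop("weight and z matrices must cover the same pairs")
  ids <- rownames(weights)
  keep <- weights > w_min & abs(zscores) >= z_min
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                      weight = weights[keep], zscore = zscores[keep],
                      stringsAsFactors = FALSE)
  edges <- canonicalize_edges(edges)
  structure(list(
    nodes = sort(unique(c(edges$node_a, edges$node_b))),
    edges = edges,
    provenance = c(list(z_min = z_min, w_min = w_min), provenance)
  ), class = "WeightedNetwork")
}

#' Assemble a network from an edge data frame
#'
#' Wraps an already-thresholded edge table (e.g. from [read_edge_list()])
#' as a `WeightedNetwork`.
#'
#' @param edges Data frame with columns `node_a`, `node_b` and optionally
#'   `weight`, `zscore`.
#' @param provenance Optional provenance list.
#' @return A `WeightedNetwork`.
#' @export
as_weighted_network <- function(edges, provenance = list()) {
  if (!all(c("node_a", "node_b") %in% names(edges)))
    stop("edge table needs node_a and node_b columns")
  if (is.null(edges$weight)) edges$weight <- NA_real_
  if (is.null(edges$zscore)) edges$zscore <- NA_real_
  edges <- canonicalize_edges(edges)
  structure(list(
    nodes = sort(unique(c(edges$node_a, edges$node_b))),
    edges = edges,
    provenance = provenance
  ), class = "WeightedNetwork")
}

#' @export
print.WeightedNetwork <- function(x, ...) {
  cat(sprintf("WeightedNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (length(x$provenance))
    cat("provenance:",
        paste(names(x$provenance),
              vapply(x$provenance, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
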