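#' Read an abundance table and its sample metadata
#'
#' The abundance table is tab-separated with the protein identifier in the
#' first column and one column per sample; the metadata table maps each sample
#' id to a condition label and replicate index. Column order of the abundance
#' file is preserved.
#'
#' @param path Path to the tab-separated abundance table.
#' @param meta_path Path to the tab-separated metadata table with columns
#'   `sample_id`, `condition`, `replicate`.
#' @param scale Scale of the stored values, `"raw"` (default) or `"log2"`.
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, meta_path, scale = "raw") {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("abundance table needs >= 2 columns: ", path)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric abundance cell at row %d ('%s'), column '%s'",
                 bad[1], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  rownames(num) <- ids
  meta <- read.delim(meta_path, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  meta$replicate <- as.integer(meta$replicate)
  abundance_matrix(num, meta, scale = scale)
}

#' Write an abundance table and its sample metadata
#'
#' Inverse of [read_abundance_table()]: values are written with full double
#' precision (17 significant digits) so the round trip reproduces the matrix
#' to floating representation.
#'
#' @param mat An [abundance_matrix()].
#' @param path,meta_path Output paths for the value table and the metadata.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(mat, path, meta_path) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  df <- data.frame(protein = rownames(mat$values),
                   format(mat$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mat$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are uppercased and
#' deduplicated (gene-set matching in this package is case-insensitive on
#' the gene-symbol side).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `GeneSetCollection`),
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(f)))
    nms[i] <- f[1]
    descs[i] <- f[2]
    sets[[i]] <- unique(toupper(f[-(1:2)]))
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  names(descs) <- nms
  structure(sets, descriptions = descs, class = "GeneSetCollection")
}

# canonicalize an edge table: order endpoints lexicographically, drop
# self-loops (warning), collapse duplicate undirected edges keeping max weight
canonicalize_edges <- function(df) {
  self <- df$node_a == df$node_b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  if (!nrow(df)) return(df[, c("node_a", "node_b", "weight", "zscore")])
  swap <- df$node_a > df$node_b
  tmp <- df$node_a[swap]
  df$node_a[swap] <- df$node_b[swap]
  df$node_b[swap] <- tmp
  key <- paste(df$node_a, df$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$weight)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
  }
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a plain-text edge list
#'
#' Accepts 2-4 column whitespace- or tab-delimited files: two node columns
#' and optional weight and z-score columns. A header line is auto-detected
#' (first line whose third field, if present, is non-numeric); this can be
#' overridden. Edges are canonicalized (endpoints ordered lexicographically),
#' self-loops are dropped with a warning, and duplicate undirected edges are
#' collapsed keeping the maximum weight.
#'
#' @param path Path to the edge-list file.
#' @param header `"auto"` (default), `"yes"` or `"no"`.
#' @param sep Field separator; `NULL` (default) splits on any whitespace.
#' @return A data frame with columns `node_a`, `node_b`, `weight`, `zscore`
#'   (missing weight column is filled with `NA`).
#' @export
read_edge_list <- function(path, header = c("auto", "yes", "no"), sep = NULL) {
  header <- match.arg(header)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list: ", path)
  split1 <- function(x) {
    if (is.null(sep)) strsplit(trimws(x), "[ \t]+")[[1]]
    else strsplit(x, sep, fixed = TRUE)[[1]]
  }
  f1 <- split1(lines[[1]])
  has_header <- switch(header,
    yes = TRUE, no = FALSE,
    auto = length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3]))))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) stop("edge list has a header but no data: ", path)
  parts <- lapply(lines, split1)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    off <- which(nf < 2)[1] + has_header
    stop(sprintf("unreadable edge-list line %d (need >= 2 fields)", off))
  }
  getcol <- function(i, numeric = FALSE) {
    v <- vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_,
                character(1))
    if (!numeric) return(v)
    v[v %in% c("NA", "NaN")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      off <- which(is.na(num) & !is.na(v))[1] + has_header
      stop(sprintf("unreadable edge-list line %d (non-numeric value '%s')",
                   off, v[is.na(num) & !is.na(v)][1]))
    }
    num
  }
  df <- data.frame(node_a = getcol(1), node_b = getcol(2),
                   weight = getcol(3, numeric = TRUE),
                   zscore = getcol(4, numeric = TRUE),
                   stringsAsFactors = FALSE)
  canonicalize_edges(df)
}

#' Write a network's edge list
#'
#' One edge per line, `node_a<TAB>node_b<TAB>weight<TAB>zscore` with six
#' decimal places, in lexicographic edge order, preceded by a header line.
#' `read_edge_list()` on the output reproduces the edge set.
#'
#' @param network A `WeightedNetwork` (see [threshold_network()]) or a
#'   canonical edge data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  edges <- if (inherits(network, "WeightedNetwork")) network$edges else network
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tweight\tzscore", con)
  if (!nrow(edges)) {
    warning("writing an empty network: ", path)
    return(invisible(path))
  }
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  writeLines(paste(edges$node_a, edges$node_b, fmt(edges$weight),
                   fmt(edges$zscore), sep = "\t"), con)
  invisible(path)
}
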