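#' Construct an abundance matrix
#'
#' Container for a proteins x samples abundance table together with per-sample
#' metadata (condition label and replicate index). Values are either raw
#' (non-negative reporter-ion sums) or log2-transformed; the scale is tracked
#' explicitly so that downstream operations can refuse input on the wrong
#' scale.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns, with
#'   unique rownames (protein ids) and colnames (sample ids).
#' @param sample_meta Data frame with columns `sample_id`, `condition`
#'   (one of `"O19"`, `"O1"`, `"O1_CyA"`) and `replicate` (integer >= 1).
#'   Rows may be in any order; they are matched to `colnames(values)`.
#' @param scale Either `"raw"` or `"log2"`.
#'
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values`, `sample_meta` (reordered to column order) and `scale`.
#' @export
abundance_matrix <- function(values, sample_meta, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(sample_meta)))
    stop("'sample_meta' needs columns: ", paste(req, collapse = ", "))
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta))
    stop("sample(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  bad <- setdiff(unique(sample_meta$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = ", "), ")")
  if (any(is.na(values)))
    stop("missing abundance cells are not allowed")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale abundances must be non-negative")
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$sample_meta$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

# columns (sample indices) belonging to one condition
condition_columns <- function(mat, condition) {
  which(mat$sample_meta$condition == condition)
}

# subset proteins, preserving metadata
subset_proteins <- function(mat, keep) {
  mat$values <- mat$values[keep, , drop = FALSE]
  mat
}
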