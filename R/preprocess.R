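#' Remove low-abundance proteins
#'
#' A protein is retained only if its raw abundance reaches `min_count` in
#' every sample (default reading of "at least one count per
#' experiment/replicate"). Set `per_sample = FALSE` to apply the alternative
#' reading, a threshold on the mean across samples.
#'
#' @param mat An [abundance_matrix()] on the raw scale.
#' @param min_count Non-negative abundance threshold (default 1).
#' @param per_sample If `TRUE` (default) every sample must reach `min_count`;
#'   if `FALSE` the across-sample mean must.
#' @return A list with elements `matrix` (the filtered [abundance_matrix()])
#'   and `report` (a `FilterReport` list of input/removed/output counts and
#'   the thresholds used).
#' @export
filter_low_abundance <- function(mat, min_count = 1, per_sample = TRUE) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "raw")
    stop("low-abundance filtering requires raw-scale abundances")
  if (min_count < 0) stop("'min_count' must be >= 0")
  keep <- if (per_sample) {
    apply(mat$values >= min_count, 1, all)
  } else {
    rowMeans(mat$values) >= min_count
  }
  out <- subset_proteins(mat, keep)
  report <- list(
    n_input = nrow(mat$values),
    n_removed_low_abundance = sum(!keep),
    n_removed_low_cv = 0L,
    n_output = sum(keep),
    thresholds = list(min_count = min_count, per_sample = per_sample)
  )
  list(matrix = out, report = report)
}

#' Log2-transform raw abundances
#'
#' @param mat An [abundance_matrix()] on the raw scale with strictly
#'   positive values (guaranteed after [filter_low_abundance()] with
#'   `min_count >= 1`).
#' @return The matrix with `values = log2(raw)` and scale `"log2"`.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "raw") stop("matrix is already log2-transformed")
  if (any(mat$values <= 0))
    stop("non-positive abundance value(s); apply filter_low_abundance() ",
         "with min_count >= 1 before log2_transform()")
  mat$values <- log2(mat$values)
  mat$scale <- "log2"
  mat
}

#' Filter proteins by coefficient of variation
#'
#' Retains proteins whose coefficient of variation (sd/mean across all
#' samples, population sd with denominator n) is at least `min_cv`. The CV
#' is computed on raw abundances by default; `on_scale = "log2"` switches to
#' the log2 values of a log2-scale matrix.
#'
#' @param mat An [abundance_matrix()]; raw scale unless `on_scale = "log2"`.
#' @param min_cv Minimum coefficient of variation (default 0.01).
#' @param on_scale Scale on which the CV is computed, `"raw"` (default) or
#'   `"log2"`.
#' @return A list with `matrix` and `report`, as in
#'   [filter_low_abundance()].
#' @export
cv_filter <- function(mat, min_cv = 0.01, on_scale = c("raw", "log2")) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  on_scale <- match.arg(on_scale)
  if (mat$scale != on_scale)
    stop(sprintf("cv_filter on the %s scale requires a %s-scale matrix",
                 on_scale, on_scale))
  n <- ncol(mat$values)
  mu <- rowMeans(mat$values)
  pop_sd <- sqrt(rowMeans(mat$values^2) - mu^2)
  pop_sd[pop_sd < 0] <- 0 # numerical guard
  cv <- pop_sd / mu
  undef <- mu == 0
  if (any(undef)) {
    warning(sum(undef), " protein(s) with zero mean removed (CV undefined)")
    cv[undef] <- NA_real_
  }
  keep <- !is.na(cv) & cv >= min_cv
  out <- subset_proteins(mat, keep)
  report <- list(
    n_input = nrow(mat$values),
    n_removed_low_abundance = 0L,
    n_removed_low_cv = sum(!keep),
    n_output = sum(keep),
    thresholds = list(min_cv = min_cv, on_scale = on_scale)
  )
  list(matrix = out, report = report)
}

#' Per-sample normality diagnostics
#'
#' Shapiro-Wilk statistic and p-value for each sample's log2 abundance
#' distribution, optionally with quantile-quantile plots written as PNG
#' files. Advisory only: nothing is filtered. Samples larger than 5000
#' proteins are subsampled (deterministically, by evenly spaced order
#' statistics) to the Shapiro-Wilk limit.
#'
#' @param mat An [abundance_matrix()] on the log2 scale.
#' @param plot_dir Directory for QQ plots, or `NULL` (default) to skip
#'   plotting.
#' @return Data frame with columns `sample_id`, `shapiro_w`, `shapiro_p`.
#' @export
qq_normality_check <- function(mat, plot_dir = NULL) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "log2") stop("normality check expects log2-scale values")
  if (nrow(mat$values) < 3)
    stop("Shapiro-Wilk needs at least 3 proteins per sample")
  if (!is.null(plot_dir) && !dir.exists(plot_dir))
    dir.create(plot_dir, recursive = TRUE)
  res <- lapply(colnames(mat$values), function(s) {
    x <- mat$values[, s]
    if (length(x) > 5000) {
      x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
    }
    sw <- shapiro.test(x)
    if (!is.null(plot_dir)) {
      grDevices::png(file.path(plot_dir, paste0("qq_", s, ".png")),
                     width = 480, height = 480)
      stats::qqnorm(x, main = paste("QQ plot:", s))
      stats::qqline(x)
      grDevices::dev.off()
    }
    data.frame(sample_id = s, shapiro_w = unname(sw$statistic),
               shapiro_p = sw$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
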