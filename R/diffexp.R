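#' Fit per-protein condition means
#'
#' One-way layout on the log2 scale: the coefficient for each condition is
#' the mean log2 abundance of its replicates, and the residual variance is
#' pooled across conditions with `N - k` degrees of freedom (N samples, k
#' conditions).
#'
#' @param mat An [abundance_matrix()] on the log2 scale with at least two
#'   replicates in every condition.
#' @return A `ModelFit` list: `coefficients` (proteins x conditions matrix of
#'   means), `sigma2` (pooled residual variance per protein), `df_residual`,
#'   `n_per_condition`, `conditions`.
#' @export
fit_condition_means <- function(mat) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "log2") stop("fit_condition_means expects log2-scale data")
  conds <- intersect(CONDITIONS, unique(mat$sample_meta$condition))
  ncond <- vapply(conds, function(cc) length(condition_columns(mat, cc)),
                  integer(1))
  if (any(ncond < 2))
    stop("condition(s) with < 2 replicates: ",
         paste(conds[ncond < 2], collapse = ", "))
  means <- vapply(conds, function(cc) {
    rowMeans(mat$values[, condition_columns(mat, cc), drop = FALSE])
  }, numeric(nrow(mat$values)))
  if (is.null(dim(means)))
    means <- matrix(means, nrow = 1, dimnames = list(rownames(mat$values), conds))
  rss <- rowSums((mat$values -
                    means[, mat$sample_meta$condition, drop = FALSE])^2)
  df <- ncol(mat$values) - length(conds)
  if (df <= 0) stop("no residual degrees of freedom")
  structure(list(
    coefficients = means,
    sigma2 = rss / df,
    df_residual = df,
    n_per_condition = ncond,
    conditions = conds
  ), class = "ModelFit")
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone, nearly
# linear in 1/y), as in the standard moderated-t hyperparameter fit.
trigamma_inverse <- function(y, tol = 1e-8, maxit = 100) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < tol) return(x)
  }
  warning("trigamma inversion did not converge in ", maxit, " iterations")
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks each protein's residual variance toward an ensemble prior by
#' fitting a scaled-F (equivalently, scaled inverse-chi-squared prior) model
#' to the observed variances: the mean and variance of `log(s_g^2)` are
#' matched to the theoretical moments of a log scaled-F distribution via
#' digamma/trigamma inversion, giving prior degrees of freedom `d0` and
#' prior variance `s02`. Posterior variances are
#' `(d0*s02 + d_g*s_g^2) / (d0 + d_g)`.
#'
#' When the moment equation has no positive solution (observed variances no
#' more dispersed than chi-squared sampling noise), `d0 = Inf` and every
#' posterior variance equals `s02`.
#'
#' @param fit A `ModelFit` from [fit_condition_means()] with at least 50
#'   proteins.
#' @param skip If `TRUE`, moderation is disabled (`d0 = 0`): posterior
#'   variances equal the per-protein variances and the downstream test is
#'   the classical pooled t.
#' @return A `ModeratedFit`: the `ModelFit` plus `d0`, `s02`, `s2_post`.
#' @export
moderate_variances <- function(fit, skip = FALSE) {
  stopifnot(inherits(fit, "ModelFit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (skip) {
    out <- c(unclass(fit), list(d0 = 0, s02 = NA_real_, s2_post = s2))
    return(structure(out, class = c("ModeratedFit", "ModelFit")))
  }
  if (length(s2) < 50)
    stop("moderation needs >= 50 proteins to estimate the prior")
  if (all(s2 == 0)) stop("all residual variances are zero; degenerate data")
  pos <- s2 > 0
  if (sum(pos) < 50)
    stop("fewer than 50 proteins with positive residual variance")
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # variances no more dispersed than chi-squared sampling noise: point-mass
    # prior at the ensemble mean
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  names(s2_post) <- names(s2)
  out <- c(unclass(fit), list(d0 = d0, s02 = s02, s2_post = s2_post))
  structure(out, class = c("ModeratedFit", "ModelFit"))
}

#' Moderated-t contrast between two conditions
#'
#' For contrast "A_vs_B", `log2FC = mean(A) - mean(B)`; the moderated t is
#' `log2FC / sqrt(s2_post * (1/nA + 1/nB))` with `d0 + d_g` degrees of
#' freedom (normal tail when `d0 = Inf`). Two-sided p-values.
#'
#' @param mfit A `ModeratedFit` from [moderate_variances()].
#' @param contrast One of `"O19_vs_O1"`, `"O19_vs_O1CyA"`, `"O1_vs_O1CyA"`.
#' @param p_max,lfc_min Thresholds for the DE flag: differential proteins
#'   have `p <= p_max` and `|log2FC| >= lfc_min`.
#' @return A `ContrastResult` data frame: `protein`, `log2FC`, `t`,
#'   `p_value`, `adj_p` (Benjamini-Hochberg, reported for transparency; the
#'   DE flag uses the raw p-value), `de`; attributes `contrast`, `p_max`,
#'   `lfc_min`.
#' @export
compute_contrast <- function(mfit, contrast, p_max = 0.01, lfc_min = 0.5) {
  stopifnot(inherits(mfit, "ModeratedFit"))
  if (!contrast %in% names(CONTRASTS))
    stop("unknown contrast '", contrast, "'; expected one of: ",
         paste(names(CONTRASTS), collapse = ", "))
  ab <- CONTRASTS[[contrast]]
  if (!all(ab %in% mfit$conditions))
    stop("contrast '", contrast, "' references condition(s) absent from the fit")
  lfc <- mfit$coefficients[, ab[1]] - mfit$coefficients[, ab[2]]
  nA <- mfit$n_per_condition[[ab[1]]]
  nB <- mfit$n_per_condition[[ab[2]]]
  se <- sqrt(mfit$s2_post * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- mfit$d0 + mfit$df_residual
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = df_total)
  p <- pmin(p, 1)
  res <- data.frame(
    protein = rownames(mfit$coefficients),
    log2FC = unname(lfc),
    t = unname(tstat),
    p_value = unname(p),
    adj_p = unname(p.adjust(p, method = "BH")),
    stringsAsFactors = FALSE
  )
  res$de <- res$p_value <= p_max & abs(res$log2FC) >= lfc_min
  attr(res, "contrast") <- contrast
  attr(res, "p_max") <- p_max
  attr(res, "lfc_min") <- lfc_min
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Call differentially expressed proteins
#'
#' A protein is differential when its raw p-value is at most `p_max` and its
#' absolute log2 fold change is at least `lfc_min` (defaults 0.01 and 0.5).
#' No multiplicity adjustment gates the call; BH-adjusted p-values are
#' carried in the result table for reference.
#'
#' @param result A `ContrastResult` from [compute_contrast()].
#' @param p_max,lfc_min Thresholds (defaults 0.01, 0.5).
#' @return Character vector of differential protein ids.
#' @export
call_de <- function(result, p_max = 0.01, lfc_min = 0.5) {
  stopifnot(inherits(result, "ContrastResult"))
  if (p_max <= 0 || lfc_min < 0) stop("thresholds must be positive")
  result$protein[result$p_value <= p_max & abs(result$log2FC) >= lfc_min]
}

#' Classify treatment-restored proteins
#'
#' A protein is "restored" when the drug returns its hypoxic abundance to
#' the normoxic level: differential in O19_vs_O1 AND differential in
#' O1_vs_O1CyA AND NOT differential in O19_vs_O1CyA, with differential
#' defined as in [call_de()].
#'
#' @param results Named list with the three `ContrastResult`s
#'   (`O19_vs_O1`, `O19_vs_O1CyA`, `O1_vs_O1CyA`).
#' @param p_max,lfc_min Thresholds passed to [call_de()].
#' @return Character vector of restored protein ids.
#' @export
classify_restored <- function(results, p_max = 0.01, lfc_min = 0.5) {
  need <- names(CONTRASTS)
  if (!all(need %in% names(results)))
    stop("need all three contrasts: ", paste(need, collapse = ", "))
  de <- lapply(results[need], call_de, p_max = p_max, lfc_min = lfc_min)
  setdiff(intersect(de$O19_vs_O1, de$O1_vs_O1CyA), de$O19_vs_O1CyA)
}

#' Replicate-paired log2 fold changes
#'
#' Per-protein log2 fold change computed replicate-wise: the value in
#' replicate i of condition A minus the value in replicate i of condition B
#' (paired by replicate index), then the median across replicates. This is
#' the per-protein quantity entering the module reversal test.
#'
#' @param mat An [abundance_matrix()] on the log2 scale.
#' @param contrast One of the three contrast names.
#' @return Named numeric vector (one median log2FC per protein).
#' @export
replicate_wise_lfc <- function(mat, contrast) {
  stopifnot(inherits(mat, "AbundanceMatrix"))
  if (mat$scale != "log2") stop("replicate_wise_lfc expects log2-scale data")
  if (!contrast %in% names(CONTRASTS))
    stop("unknown contrast '", contrast, "'")
  ab <- CONTRASTS[[contrast]]
  ma <- mat$sample_meta
  ra <- ma$replicate[ma$condition == ab[1]]
  rb <- ma$replicate[ma$condition == ab[2]]
  common <- intersect(ra, rb)
  if (!length(common)) stop("no shared replicate indices between ",
                            ab[1], " and ", ab[2])
  diffs <- vapply(sort(common), function(r) {
    ia <- which(ma$condition == ab[1] & ma$replicate == r)
    ib <- which(ma$condition == ab[2] & ma$replicate == r)
    mat$values[, ia] - mat$values[, ib]
  }, numeric(nrow(mat$values)))
  if (is.null(dim(diffs)))
    diffs <- matrix(diffs, nrow = 1,
                    dimnames = list(rownames(mat$values), NULL))
  apply(diffs, 1, median)
}
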