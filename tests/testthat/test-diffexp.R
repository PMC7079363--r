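test_that("condition means and pooled variances match hand computation", {
  # 2 conditions x 2 replicates, values (0,2 | 1,3): means 1 and 2,
  # residual SS = 2+2 = 4 over df = 4-2 = 2 -> s2 = 2
  vals <- matrix(2^c(0, 2, 1, 3), 1, 4,
                 dimnames = list("P1", c("a1", "a2", "b1", "b2")))
  mat <- abundance_matrix(vals,
    data.frame(sample_id = c("a1", "a2", "b1", "b2"),
               condition = c("O19", "O19", "O1", "O1"),
               replicate = c(1, 2, 1, 2)), scale = "raw")
  fit <- fit_condition_means(log2_transform(mat))
  expect_equal(unname(fit$coefficients["P1", c("O19", "O1")]), c(1, 2))
  expect_equal(unname(fit$sigma2), 2)
  expect_equal(fit$df_residual, 2)

  # identical replicates -> zero residual variance
  same <- make_log2_matrix(matrix(rep(c(1, 2, 3), each = 3), 1, 9))
  expect_equal(unname(fit_condition_means(same)$sigma2), 0)

  # a condition with a single replicate is refused
  solo <- abundance_matrix(
    matrix(1, 1, 3, dimnames = list("P1", c("a", "b", "c"))),
    data.frame(sample_id = c("a", "b", "c"),
               condition = c("O19", "O19", "O1"), replicate = c(1, 2, 1)),
    scale = "raw")
  expect_error(fit_condition_means(log2_transform(solo)), "O1")
})

test_that("pooled residual variance is unbiased on null data", {
  set.seed(61)
  sigma <- 0.4
  vals <- matrix(rnorm(5000 * 9, 20, sigma), 5000, 9)
  fit <- fit_condition_means(make_log2_matrix(vals))
  expect_equal(mean(fit$sigma2), sigma^2, tolerance = 0.05 * sigma^2)
})

test_that("variance moderation matches the limma empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  sim <- generate_synthetic(synthetic_config(n_proteins = 400, seed = 3))
  lm2 <- log2_transform(filter_low_abundance(sim$matrix)$matrix)
  fit <- fit_condition_means(lm2)
  mfit <- moderate_variances(fit)

  cond <- factor(lm2$sample_meta$condition, levels = c("O19", "O1", "O1_CyA"))
  design <- stats::model.matrix(~0 + cond)
  colnames(design) <- levels(cond)
  lf <- limma::lmFit(lm2$values, design)
  cm <- limma::makeContrasts(O19 - O1, levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))

  expect_equal(mfit$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(mfit$s02, eb$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mfit$s2_post), unname(eb$s2.post), tolerance = 1e-10)
  mine <- compute_contrast(mfit, "O19_vs_O1")
  expect_equal(mine$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("moderation degenerates correctly at the boundary cases", {
  # all sigma2 equal -> infinite prior df, posterior = that value
  vals <- matrix(rnorm(60 * 9, 20, 0.3), 60, 9)
  lm2 <- make_log2_matrix(vals)
  fit <- fit_condition_means(lm2)
  fit$sigma2 <- rep(0.09, 60)
  mfit <- moderate_variances(fit)
  expect_identical(mfit$d0, Inf)
  expect_equal(mfit$s02, 0.09, tolerance = 1e-6)
  expect_equal(unname(mfit$s2_post), rep(0.09, 60), tolerance = 1e-6)

  # skip flag: identity
  mskip <- moderate_variances(fit, skip = TRUE)
  expect_identical(unname(mskip$s2_post), unname(fit$sigma2))

  fit$sigma2 <- rep(0, 60)
  expect_error(moderate_variances(fit), "degenerate")
})

test_that("the prior df is recovered from data simulated under the model", {
  # true variances from a scaled inverse-chi-squared prior with d0 = 4,
  # s02 = 1; observed s2 ~ v * chisq(d)/d
  set.seed(71)
  d0 <- 4; s02 <- 1; d <- 6; n_prot <- 5000
  v <- d0 * s02 / rchisq(n_prot, d0)
  s2 <- v * rchisq(n_prot, d) / d
  fit <- structure(list(sigma2 = s2, df_residual = d,
                        coefficients = matrix(0, n_prot, 3,
                          dimnames = list(sprintf("P%d", 1:n_prot),
                                          c("O19", "O1", "O1_CyA"))),
                        n_per_condition = c(O19 = 3, O1 = 3, O1_CyA = 3),
                        conditions = c("O19", "O1", "O1_CyA")),
                   class = "ModelFit")
  mfit <- moderate_variances(fit)
  expect_gt(mfit$d0, d0 * 0.7)
  expect_lt(mfit$d0, d0 * 1.3)
  # shrinkage: posterior between the observation and the prior
  expect_true(all(mfit$s2_post >= pmin(s2, mfit$s02) - 1e-12))
  expect_true(all(mfit$s2_post <= pmax(s2, mfit$s02) + 1e-12))
})

test_that("with moderation off the contrast equals the classical pooled t", {
  set.seed(81)
  vals <- matrix(rnorm(80 * 4, 5, 1), 80, 4,
                 dimnames = list(sprintf("P%d", 1:80),
                                 c("a1", "a2", "b1", "b2")))
  mat <- abundance_matrix(2^vals,
    data.frame(sample_id = c("a1", "a2", "b1", "b2"),
               condition = c("O19", "O19", "O1", "O1"),
               replicate = c(1, 2, 1, 2)), scale = "raw")
  mfit <- moderate_variances(fit_condition_means(log2_transform(mat)),
                             skip = TRUE)
  res <- compute_contrast(mfit, "O19_vs_O1")
  # independent textbook pooled-variance two-sample t
  oracle <- apply(vals, 1, function(x) {
    m1 <- mean(x[1:2]); m2 <- mean(x[3:4])
    sp2 <- (sum((x[1:2] - m1)^2) + sum((x[3:4] - m2)^2)) / 2
    tt <- (m1 - m2) / sqrt(sp2 * (1 / 2 + 1 / 2))
    c(t = tt, p = 2 * pt(-abs(tt), df = 2))
  })
  expect_equal(res$t, unname(oracle["t", ]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(oracle["p", ]), tolerance = 1e-10)
})

test_that("contrasts are antisymmetric and calibrated under the null", {
  set.seed(91)
  vals <- matrix(rnorm(2000 * 9, 20, 0.25), 2000, 9)
  mfit <- moderate_variances(fit_condition_means(make_log2_matrix(vals)))
  r1 <- compute_contrast(mfit, "O19_vs_O1")
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_equal(r1$p_value[r1$log2FC == 0],
               rep(1, sum(r1$log2FC == 0)))

  # swapping the contrast orientation negates log2FC/t, keeps p
  swapped <- compute_contrast(mfit, "O1_vs_O1CyA")
  manual <- mfit$coefficients[, "O1"] - mfit$coefficients[, "O1_CyA"]
  expect_equal(swapped$log2FC, unname(manual))

  # DE set shrinks as thresholds tighten
  d1 <- call_de(r1, p_max = 0.05, lfc_min = 0.1)
  d2 <- call_de(r1, p_max = 0.01, lfc_min = 0.1)
  d3 <- call_de(r1, p_max = 0.01, lfc_min = 0.5)
  expect_true(all(d2 %in% d1))
  expect_true(all(d3 %in% d2))
})

test_that("DE calling applies both the p and fold-change arms", {
  res <- structure(data.frame(protein = c("A", "B", "C"),
                              log2FC = c(0.4, 0.6, -0.7),
                              t = c(3, 3, -3),
                              p_value = c(0.005, 0.005, 0.5),
                              adj_p = c(0.01, 0.01, 0.6),
                              de = c(FALSE, TRUE, FALSE)),
                   class = c("ContrastResult", "data.frame"))
  expect_identical(call_de(res), "B") # A fails lfc, C fails p
})

test_that("restored proteins are those rescued by the drug", {
  mk <- function(p, lfc) {
    structure(data.frame(protein = sprintf("P%d", seq_along(p)),
                         log2FC = lfc, t = 0, p_value = p, adj_p = p,
                         de = p <= 0.01 & abs(lfc) >= 0.5),
              class = c("ContrastResult", "data.frame"))
  }
  # P1: DE everywhere -> not restored; P2: the restored pattern;
  # P3: no effects -> not restored
  res <- list(
    O19_vs_O1    = mk(c(0.001, 0.001, 0.9), c(1, 1, 0)),
    O19_vs_O1CyA = mk(c(0.001, 0.9, 0.9), c(1, 0, 0)),
    O1_vs_O1CyA  = mk(c(0.001, 0.001, 0.9), c(1, -1, 0))
  )
  expect_identical(classify_restored(res), "P2")
})

test_that("planted restored proteins are recovered with high probability", {
  hits <- 0L
  n_runs <- 100
  for (s in seq_len(n_runs)) {
    sim <- generate_synthetic(synthetic_config(
      n_proteins = 100, seed = 1000 + s, sigma = 0.2, delta = 1.0,
      de_frac = 0, restored_frac = 0.01, low_abundance_frac = 0,
      low_cv_frac = 0,
      modules = data.frame(size = integer(), rho = numeric(),
                           o1_shift = numeric())))
    planted <- sim$truth$labels$protein[sim$truth$labels$label == "restored"]
    lm2 <- log2_transform(sim$matrix)
    mfit <- moderate_variances(fit_condition_means(lm2))
    ctr <- lapply(setNames(nm = c("O19_vs_O1", "O19_vs_O1CyA", "O1_vs_O1CyA")),
                  function(cn) compute_contrast(mfit, cn))
    if (planted %in% classify_restored(ctr)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("replicate-paired fold changes are medians of paired differences", {
  vals <- matrix(0, 1, 9, dimnames = list("P1", NULL))
  # O19 replicates: 5, 6, 7; O1 replicates: 1, 2, 3 -> diffs 4,4,4
  vals[1, ] <- c(5, 6, 7, 1, 2, 3, 0, 0, 0)
  mat <- make_log2_matrix(vals)
  lfc <- replicate_wise_lfc(mat, "O19_vs_O1")
  expect_equal(unname(lfc["P1"]), 4)
  lfc2 <- replicate_wise_lfc(mat, "O1_vs_O1CyA")
  expect_equal(unname(lfc2["P1"]), 2) # median of (1,2,3)
})
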