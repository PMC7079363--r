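test_that("absolute Pearson weights match an independent computation", {
  # duplicated and perfectly anticorrelated rows have weight 1
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  vals <- rbind(base, base, rev(base))
  lm2 <- make_log2_matrix(vals, proteins = c("A", "B", "C"))
  w <- pairwise_abs_pearson(lm2)
  expect_equal(w["A", "B"], 1)
  expect_equal(w["A", "C"], 1)
  expect_true(is.na(w["A", "A"]))

  # textbook formula oracle on an irregular pair (6 samples)
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  vals6 <- rbind(x, y)
  mat6 <- abundance_matrix(
    matrix(2^vals6, 2, 6, dimnames = list(c("X", "Y"), sprintf("s%d", 1:6))),
    data.frame(sample_id = sprintf("s%d", 1:6),
               condition = rep(c("O19", "O1"), each = 3),
               replicate = rep(1:3, 2)), scale = "raw")
  w6 <- pairwise_abs_pearson(log2_transform(mat6))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(w6["X", "Y"], abs(r_oracle), tolerance = 1e-12)

  const <- make_log2_matrix(rbind(base, rep(1, 9)))
  expect_error(pairwise_abs_pearson(const), "constant")
})

test_that("permutation z-scores are deterministic and seed-gated", {
  set.seed(131)
  lm2 <- make_log2_matrix(matrix(rnorm(20 * 9, 20, 0.3), 20, 9))
  z1 <- permutation_zscores(lm2, n_perm = 20, seed = 7)
  z2 <- permutation_zscores(lm2, n_perm = 20, seed = 7)
  expect_identical(z1, z2)
  z3 <- permutation_zscores(lm2, n_perm = 20, seed = 8)
  expect_false(identical(z1, z3))
  expect_error(permutation_zscores(lm2, n_perm = 20), "seed")
  expect_error(permutation_zscores(lm2, n_perm = 1, seed = 1), "n_perm")
})

test_that("duplicated rows earn large z-scores across seeded runs", {
  set.seed(141)
  hits <- 0L
  n_runs <- 200
  for (r in seq_len(n_runs)) {
    row <- rnorm(9, 20, 0.5)
    lm2 <- make_log2_matrix(rbind(row, row + rnorm(9, 0, 1e-3)))
    z <- suppressWarnings(permutation_zscores(lm2, n_perm = 50, seed = r))
    if (z[1, 2] > 1.5) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("thresholding applies both arms with the stated strictness", {
  ids <- c("A", "B", "C", "D")
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  z <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w[1, 2] <- w[2, 1] <- 0.5   # exactly at the bound -> removed
  z[1, 2] <- z[2, 1] <- 99
  w[1, 3] <- w[3, 1] <- 0.9   # z too small -> removed
  z[1, 3] <- z[3, 1] <- 1.49
  w[2, 4] <- w[4, 2] <- 0.9   # survives
  z[2, 4] <- z[4, 2] <- -1.6  # |z| counts
  net <- threshold_network(w, z)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$node_a, "B")
  expect_identical(net$edges$node_b, "D")
  # isolated proteins are dropped from the node set
  expect_identical(net$nodes, c("B", "D"))
})

test_that("the edge set shrinks monotonically in both thresholds", {
  set.seed(151)
  lm2 <- make_log2_matrix(matrix(rnorm(30 * 9, 20, 0.3), 30, 9))
  w <- pairwise_abs_pearson(lm2)
  z <- suppressWarnings(permutation_zscores(lm2, n_perm = 30, seed = 3))
  key <- function(net) paste(net$edges$node_a, net$edges$node_b)
  e_base <- key(threshold_network(w, z, z_min = 0.5, w_min = 0.2))
  e_z <- key(threshold_network(w, z, z_min = 1.2, w_min = 0.2))
  e_zw <- key(threshold_network(w, z, z_min = 1.2, w_min = 0.5))
  expect_true(all(e_z %in% e_base))
  expect_true(all(e_zw %in% e_z))
})

test_that("planted co-expression blocks survive thresholding", {
  sim <- generate_synthetic(synthetic_config(
    n_proteins = 120, seed = 17, de_frac = 0, restored_frac = 0,
    low_abundance_frac = 0, low_cv_frac = 0,
    modules = data.frame(size = c(25, 25), rho = 0.9, o1_shift = 0)))
  lm2 <- log2_transform(sim$matrix)
  w <- pairwise_abs_pearson(lm2)
  z <- suppressWarnings(permutation_zscores(lm2, n_perm = 50, seed = 17))
  net <- threshold_network(w, z)
  lab <- sim$truth$labels
  key <- paste(net$edges$node_a, net$edges$node_b)
  rate <- function(mem_a, mem_b) {
    prs <- expand.grid(a = mem_a, b = mem_b, stringsAsFactors = FALSE)
    prs <- prs[prs$a < prs$b, ]
    mean(paste(prs$a, prs$b) %in% key)
  }
  m1 <- lab$protein[!is.na(lab$module) & lab$module == 1]
  m2 <- lab$protein[!is.na(lab$module) & lab$module == 2]
  within_rate <- (rate(m1, m1) + rate(m2, m2)) / 2
  between_rate <- mean(paste(pmin(rep(m1, each = length(m2)), m2),
                             pmax(rep(m1, each = length(m2)), m2)) %in% key)
  expect_gte(within_rate, 0.8)
  expect_lt(between_rate, within_rate / 2)
})

test_that("within-module correlation rises with the factor loading", {
  mean_within <- vapply(c(0.3, 0.6, 0.9), function(rho) {
    sim <- generate_synthetic(synthetic_config(
      n_proteins = 40, seed = 19, de_frac = 0, restored_frac = 0,
      low_abundance_frac = 0, low_cv_frac = 0,
      modules = data.frame(size = 30, rho = rho, o1_shift = 0)))
    lm2 <- log2_transform(sim$matrix)
    w <- pairwise_abs_pearson(lm2)
    mean(w[1:30, 1:30][upper.tri(w[1:30, 1:30])])
  }, numeric(1))
  expect_true(all(diff(mean_within) > 0))
})
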