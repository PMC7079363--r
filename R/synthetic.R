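#' Synthetic-experiment generator configuration
#'
#' Parameters of the synthetic TMT-style experiment: a 3-condition x
#' 3-replicate design with log-normal raw abundances, planted
#' hypoxia-responsive (DE) proteins, planted drug-restored proteins,
#' block-correlated co-expression modules (optionally with a module-level
#' hypoxia shift that the drug reverses), and planted low-abundance and
#' low-CV proteins for the filter stages.
#'
#' On the log2 scale, protein g in sample s is
#' `mu_g + effect(g, condition(s)) + rho_m * f_m(s) + eps`, with
#' `mu_g ~ N(mu0, tau)`, `f_m(s) ~ N(0,1)` a per-sample latent factor shared
#' within module m, and `eps ~ N(0, sigma)`. The implied within-module
#' correlation is `rho^2 / (rho^2 + sigma^2)`. DE proteins carry `+-delta`
#' at both O1 and O1_CyA; restored proteins carry `+-delta` at O1 only;
#' a module `o1_shift` is added at O1 only for every member of that module.
#' Raw abundances are `2^log2`; low-abundance proteins are shifted so their
#' smallest sample value falls below one count.
#'
#' @param n_proteins Total protein count (default 5000).
#' @param replicates Replicates per condition (default 3).
#' @param mu0,tau Baseline log2 abundance mean and between-protein sd
#'   (defaults 20 and 2, typical of summed TMT reporter intensities).
#' @param sigma Within-protein noise sd on the log2 scale (default 0.25).
#' @param de_frac Fraction of DE proteins (default 0.008, i.e. 40 of 5000),
#'   half up, half down.
#' @param delta Log2 effect size of DE and restored proteins (default 1.2).
#' @param restored_frac Fraction of individually restored proteins
#'   (default 0.002, i.e. 10 of 5000).
#' @param modules Data frame with columns `size`, `rho`, `o1_shift`
#'   describing the planted co-expression modules (default three modules of
#'   30 at loading 0.9, the first carrying an O1-only shift of 1.2 so the
#'   module reversal test has a planted positive).
#' @param low_abundance_frac,low_cv_frac Fractions of planted filter
#'   targets (defaults 0.004 each).
#' @param seed Mandatory integer seed.
#' @return A validated `GeneratorConfig` list.
#' @export
synthetic_config <- function(n_proteins = 5000, replicates = 3,
                             mu0 = 20, tau = 2, sigma = 0.25,
                             de_frac = 0.008, delta = 1.2,
                             restored_frac = 0.002,
                             modules = data.frame(size = c(30, 30, 30),
                                                  rho = c(0.9, 0.9, 0.9),
                                                  o1_shift = c(1.2, 0, 0)),
                             low_abundance_frac = 0.004,
                             low_cv_frac = 0.004, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  cfg <- list(n_proteins = as.integer(n_proteins),
              replicates = as.integer(replicates),
              mu0 = mu0, tau = tau, sigma = sigma,
              de_frac = de_frac, delta = delta,
              restored_frac = restored_frac, modules = modules,
              low_abundance_frac = low_abundance_frac,
              low_cv_frac = low_cv_frac, seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 1, cfg$replicates >= 2,
            cfg$tau > 0, cfg$sigma > 0, cfg$delta > 0)
  fr <- c(cfg$de_frac, cfg$restored_frac, cfg$low_abundance_frac,
          cfg$low_cv_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!is.null(cfg$modules) && nrow(cfg$modules)) {
    if (!all(c("size", "rho") %in% names(cfg$modules)))
      stop("'modules' needs columns size and rho")
    if (is.null(cfg$modules$o1_shift)) cfg$modules$o1_shift <- 0
    if (any(cfg$modules$rho <= 0)) stop("module loadings must be > 0")
  } else {
    cfg$modules <- data.frame(size = integer(), rho = numeric(),
                              o1_shift = numeric())
  }
  n_special <- round(cfg$n_proteins * sum(fr)) + sum(cfg$modules$size)
  if (n_special > cfg$n_proteins)
    stop("special fractions plus module sizes exceed n_proteins")
  class(cfg) <- "GeneratorConfig"
  cfg
}

# named-stream sub-seeds derived from the one config seed, so each draw
# category uses its own reproducible stream (all < 2^31)
stream_seed <- function(seed, stream) {
  streams <- c(baselines = 1L, effects = 2L, factors = 3L, noise = 4L,
               lowab = 5L, stage_network = 11L, stage_null = 12L)
  if (!stream %in% names(streams)) stop("unknown RNG stream: ", stream)
  as.integer((as.double(seed) * 48271 + 7919 * streams[[stream]]) %% 2147483647)
}

#' Generate a synthetic abundance matrix with ground truth
#'
#' @param config A `GeneratorConfig` from [synthetic_config()].
#' @return List with `matrix` (a raw-scale [abundance_matrix()]) and
#'   `truth` (a `SyntheticTruth`: data frame `labels` with per-protein
#'   label, module id and realized signed effect, plus the config echo).
#'   Labels are `null`, `de_up`, `de_down`, `restored`, `module_restored`
#'   (member of a module with a planted O1 shift), `low_abundance`,
#'   `low_cv`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  p <- config$n_proteins
  reps <- config$replicates
  conds <- rep(CONDITIONS, each = reps)
  n <- length(conds)
  sample_ids <- paste0(conds, "_r", rep(seq_len(reps), times = 3))
  proteins <- sprintf("P%05d", seq_len(p))

  n_de <- round(p * config$de_frac)
  n_res <- round(p * config$restored_frac)
  n_lab <- round(p * config$low_abundance_frac)
  n_lcv <- round(p * config$low_cv_frac)
  msizes <- config$modules$size

  label <- rep("null", p)
  module <- rep(NA_integer_, p)
  effect <- rep(0, p)
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }
  i_de <- take(n_de)
  i_res <- take(n_res)
  i_mod <- lapply(msizes, take)
  i_lab <- take(n_lab)
  i_lcv <- take(n_lcv)
  if (n_de) {
    sgn <- rep(c(1, -1), length.out = n_de)
    label[i_de] <- ifelse(sgn > 0, "de_up", "de_down")
    effect[i_de] <- sgn * config$delta
  }
  if (n_res) {
    sgn <- rep(c(1, -1), length.out = n_res)
    label[i_res] <- "restored"
    effect[i_res] <- sgn * config$delta
  }
  for (m in seq_along(i_mod)) {
    module[i_mod[[m]]] <- m
    sh <- config$modules$o1_shift[m]
    if (sh != 0) {
      label[i_mod[[m]]] <- "module_restored"
      effect[i_mod[[m]]] <- sh
    }
  }
  label[i_lab] <- "low_abundance"
  label[i_lcv] <- "low_cv"

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(stream_seed(config$seed, "baselines"))
  mu <- rnorm(p, config$mu0, config$tau)

  set.seed(stream_seed(config$seed, "factors"))
  factors <- matrix(rnorm(max(length(msizes), 1) * n), ncol = n)

  set.seed(stream_seed(config$seed, "noise"))
  eps <- matrix(rnorm(p * n, 0, config$sigma), p, n)
  eps[i_lcv, ] <- eps[i_lcv, ] / config$sigma * 0.003

  x <- mu + eps # recycles mu down columns
  is_o1 <- conds == "O1"
  is_hyp <- conds %in% c("O1", "O1_CyA")
  if (n_de) x[i_de, is_hyp] <- x[i_de, is_hyp] + effect[i_de]
  if (n_res) x[i_res, is_o1] <- x[i_res, is_o1] + effect[i_res]
  for (m in seq_along(i_mod)) {
    idx <- i_mod[[m]]
    x[idx, ] <- x[idx, ] +
      config$modules$rho[m] * matrix(factors[m, ], length(idx), n, byrow = TRUE)
    sh <- config$modules$o1_shift[m]
    if (sh != 0) x[idx, is_o1] <- x[idx, is_o1] + sh
  }
  # low-abundance proteins: shift so the smallest sample value is below one
  # count (raw 0.5 = log2 -1)
  if (n_lab) {
    shift <- apply(x[i_lab, , drop = FALSE], 1, min) + 1
    x[i_lab, ] <- x[i_lab, ] - shift
  }

  raw <- 2^x
  dimnames(raw) <- list(proteins, sample_ids)
  meta <- data.frame(sample_id = sample_ids, condition = conds,
                     replicate = rep(seq_len(reps), times = 3),
                     stringsAsFactors = FALSE)
  truth <- structure(list(
    labels = data.frame(protein = proteins, label = label, module = module,
                        effect = effect, stringsAsFactors = FALSE),
    config = config
  ), class = "SyntheticTruth")
  list(matrix = abundance_matrix(raw, meta, scale = "raw"), truth = truth)
}

#' Synthetic stand-in network at study scale
#'
#' Constructs a co-expression-style network with exactly 1408 nodes and
#' 1211 edges — the dimensions of the hypoxia study's thresholded network —
#' with a planted community structure: 24 dense modules of 12 nodes (a hub
#' plus a chorded ring, 22 edges each) and filler components (437 node
#' pairs and 82 triangles) emulating the many tiny components a sparse
#' thresholded network contains. This is a SYNTHETIC stand-in whose planted
#' counts are known by construction; it exercises parsing, community
#' detection and overlap machinery at realistic scale, it does not
#' reproduce the study's actual network (which is not deposited in a
#' re-usable form).
#'
#' @param seed Mandatory integer seed (edge weights/z-scores are drawn from
#'   it; the topology is fixed).
#' @param n_modules,module_size Planted module structure (defaults 24 and
#'   12; changing them changes the node/edge totals).
#' @return A `WeightedNetwork` with `provenance$planted_modules` recording
#'   the construction.
#' @export
synthetic_study_network <- function(seed, n_modules = 24, module_size = 12) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  edges <- list()
  node_id <- 0L
  new_nodes <- function(k) {
    ids <- sprintf("SYN%04d", node_id + seq_len(k))
    node_id <<- node_id + k
    ids
  }
  for (m in seq_len(n_modules)) {
    v <- new_nodes(module_size)
    hub <- v[1]
    ring <- v[-1]
    nr <- length(ring)
    edges[[length(edges) + 1L]] <- data.frame(
      node_a = c(rep(hub, nr), ring),
      node_b = c(ring, ring[c(2:nr, 1)]),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(437)) {
    v <- new_nodes(2)
    edges[[length(edges) + 1L]] <- data.frame(node_a = v[1], node_b = v[2],
                                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(82)) {
    v <- new_nodes(3)
    edges[[length(edges) + 1L]] <- data.frame(
      node_a = v[c(1, 1, 2)], node_b = v[c(2, 3, 3)],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, edges)
  df$weight <- round(runif(nrow(df), 0.55, 0.99), 6)
  df$zscore <- round(runif(nrow(df), 1.6, 4), 6)
  as_weighted_network(df, provenance = list(
    planted_modules = n_modules, module_size = module_size, seed = seed))
}

#' Recovery metrics of a pipeline run against planted truth
#'
#' Compares pipeline outputs with the generator's planted labels:
#' \itemize{
#'   \item DE precision/recall: detected set vs proteins planted with a
#'     hypoxia effect in both treated conditions (`de_up`/`de_down`), and
#'     the false-positive rate among planted nulls;
#'   \item restored precision/recall: vs individually planted restored
#'     proteins (members of a shifted module are excluded from both sides —
#'     their shared latent factor inflates per-protein variance by design);
#'   \item module recovery: Adjusted Rand Index between the planted module
#'     partition and the detected partition, restricted to planted module
#'     members;
#'   \item within-module edge recall: fraction of planted within-module
#'     pairs present as network edges.
#' }
#'
#' @param truth A `SyntheticTruth`.
#' @param de_called Character vector from [call_de()] (contrast O19_vs_O1).
#' @param restored_called Character vector from [classify_restored()].
#' @param membership Named module membership from [girvan_newman()]
#'   (or `NULL` to skip the ARI).
#' @param network A `WeightedNetwork` (or `NULL` to skip edge recall).
#' @return List of metrics; precision is `NA` when nothing was called.
#' @export
evaluate_recovery <- function(truth, de_called = NULL, restored_called = NULL,
                              membership = NULL, network = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  lab <- truth$labels
  out <- list()
  pr <- function(called, positives, negatives) {
    tp <- length(intersect(called, positives))
    list(
      recall = if (length(positives)) tp / length(positives) else NA_real_,
      precision = if (length(called)) tp / length(called) else NA_real_,
      fp_rate = if (length(negatives))
        length(intersect(called, negatives)) / length(negatives) else NA_real_
    )
  }
  nulls <- lab$protein[lab$label == "null"]
  if (!is.null(de_called)) {
    de_truth <- lab$protein[lab$label %in% c("de_up", "de_down")]
    m <- pr(de_called, de_truth, nulls)
    out$de_recall <- m$recall
    out$de_precision <- m$precision
    out$de_fp_rate <- m$fp_rate
  }
  if (!is.null(restored_called)) {
    res_truth <- lab$protein[lab$label == "restored"]
    shifted <- lab$protein[lab$label == "module_restored"]
    m <- pr(setdiff(restored_called, shifted), res_truth, nulls)
    out$restored_recall <- m$recall
    out$restored_precision <- m$precision
  }
  planted <- lab$protein[!is.na(lab$module)]
  if (!is.null(membership) && length(planted)) {
    common <- intersect(planted, names(membership))
    out$module_ari <- if (length(common) >= 2) {
      mclust::adjustedRandIndex(lab$module[match(common, lab$protein)],
                                membership[common])
    } else NA_real_
    out$module_coverage <- length(common) / length(planted)
  }
  if (!is.null(network) && length(planted)) {
    key <- paste(network$edges$node_a, network$edges$node_b)
    hits <- 0L
    total <- 0L
    for (m in unique(lab$module[!is.na(lab$module)])) {
      mem <- sort(lab$protein[!is.na(lab$module) & lab$module == m])
      prs <- utils::combn(mem, 2)
      total <- total + ncol(prs)
      hits <- hits + sum(paste(prs[1, ], prs[2, ]) %in% key)
    }
    out$within_module_edge_recall <- if (total) hits / total else NA_real_
  }
  out
}
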