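#' Pipeline configuration
#'
#' Collects every input path and threshold of the full analysis. Defaults
#' are the study's operating point: low-abundance cutoff 1 count,
#' CV cutoff 0.01, DE rule p <= 0.01 and |log2FC| >= 0.5, 50 permutations,
#' |z| >= 1.5 with weights > 0.5, module size >= 10, reversal and
#' enrichment alpha 0.05. The seed has no default: a run without an
#' explicit seed is an error.
#'
#' @param abundance,meta Paths to the abundance and metadata TSVs
#'   (`NULL` when an [abundance_matrix()] is passed to [run_pipeline()]
#'   directly).
#' @param gmt Optional path to a GMT gene-set collection.
#' @param knowledge_edges,pathway_genes Optional paths to the knowledge
#'   network edge table and the pathway gene list (one symbol per line).
#' @param id_map Optional path to a two-column protein-to-gene symbol map.
#' @param min_count,min_cv,p_max,lfc_min,n_perm,z_min,w_min,module_min_size,reversal_alpha,enrich_alpha,knowledge_min_score
#'   Thresholds; see module documentation.
#' @param seed Mandatory integer seed driving all randomness.
#' @param outdir Optional output directory for TSV/JSON artifacts.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(abundance = NULL, meta = NULL, gmt = NULL,
                            knowledge_edges = NULL, pathway_genes = NULL,
                            id_map = NULL,
                            min_count = 1, min_cv = 0.01,
                            p_max = 0.01, lfc_min = 0.5,
                            n_perm = 50, z_min = 1.5, w_min = 0.5,
                            module_min_size = 10, reversal_alpha = 0.05,
                            enrich_alpha = 0.05, knowledge_min_score = 0.4,
                            seed, outdir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory (no silent clock seed)")
  cfg <- list(abundance = abundance, meta = meta, gmt = gmt,
              knowledge_edges = knowledge_edges,
              pathway_genes = pathway_genes, id_map = id_map,
              min_count = min_count, min_cv = min_cv, p_max = p_max,
              lfc_min = lfc_min, n_perm = as.integer(n_perm),
              z_min = z_min, w_min = w_min,
              module_min_size = as.integer(module_min_size),
              reversal_alpha = reversal_alpha, enrich_alpha = enrich_alpha,
              knowledge_min_score = knowledge_min_score,
              seed = as.integer(seed), outdir = outdir)
  stopifnot(cfg$min_count >= 0, cfg$min_cv >= 0, cfg$p_max > 0,
            cfg$lfc_min >= 0, cfg$n_perm >= 2, cfg$z_min >= 0,
            cfg$w_min >= 0, cfg$module_min_size >= 1)
  for (f in c("abundance", "meta", "gmt", "knowledge_edges",
              "pathway_genes", "id_map")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config file for '", f, "' does not exist: ", cfg[[f]])
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::yaml.load_file(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

stage_msg <- function(log, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  c(log, line)
}

write_json_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: low-abundance filter, log2 transform, normality
#' diagnostics, moderated-t differential analysis over the three contrasts,
#' restored-protein classification, (optional) DE enrichment, CV filter,
#' co-expression network with permutation z-scores and dual threshold,
#' Girvan-Newman modules with size filter, module reversal tests,
#' (optional) per-module enrichment and knowledge-network comparison.
#' Every stage logs its input/output cardinalities; any failure aborts with
#' a stage-named error.
#'
#' @param config A `PipelineConfig`.
#' @param mat Optional [abundance_matrix()] (raw scale); when `NULL`, the
#'   abundance/meta paths in the config are read.
#' @return A `RunReport` list (thresholds echo, filter reports, prior
#'   estimates, DE counts, restored set, network and module summaries,
#'   reversal flags, knowledge overlap, hubs, log). When `config$outdir`
#'   is set, TSV tables, the network edge list and `report.json` are
#'   written there; the report JSON is byte-identical across reruns with
#'   the same config and seed.
#' @export
run_pipeline <- function(config, mat = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character()
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(outdir))
      write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (is.null(mat)) {
    if (is.null(config$abundance) || is.null(config$meta))
      stop("stage 'input' failed: no abundance matrix or paths supplied")
    mat <- wrap("input", read_abundance_table(config$abundance, config$meta))
  }
  log <- stage_msg(log, "input", "%d proteins x %d samples",
                   nrow(mat$values), ncol(mat$values))

  fl <- wrap("low_abundance_filter",
             filter_low_abundance(mat, min_count = config$min_count))
  log <- stage_msg(log, "low_abundance_filter", "%d -> %d proteins",
                   fl$report$n_input, fl$report$n_output)
  lmat <- wrap("log2_transform", log2_transform(fl$matrix))

  qq <- wrap("normality_check",
             qq_normality_check(lmat, plot_dir =
                                  if (is.null(outdir)) NULL
                                  else file.path(outdir, "qq")))
  save_tsv(qq, "normality_check.tsv")
  log <- stage_msg(log, "normality_check", "median Shapiro W = %.4f",
                   median(qq$shapiro_w))

  fit <- wrap("diffexp", fit_condition_means(lmat))
  mfit <- wrap("diffexp", moderate_variances(fit))
  contrasts <- lapply(names(CONTRASTS), function(cn)
    compute_contrast(mfit, cn, p_max = config$p_max,
                     lfc_min = config$lfc_min))
  names(contrasts) <- names(CONTRASTS)
  de_sets <- lapply(contrasts, call_de, p_max = config$p_max,
                    lfc_min = config$lfc_min)
  restored <- classify_restored(contrasts, p_max = config$p_max,
                                lfc_min = config$lfc_min)
  for (cn in names(contrasts))
    save_tsv(contrasts[[cn]], paste0("contrast_", cn, ".tsv"))
  log <- stage_msg(log, "diffexp",
                   "d0 = %.3g, s02 = %.3g; DE: %s; union %d; restored %d",
                   mfit$d0, mfit$s02,
                   paste(names(de_sets), lengths(de_sets), sep = "=",
                         collapse = ", "),
                   length(unique(unlist(de_sets))), length(restored))

  collection <- if (!is.null(config$gmt)) wrap("enrichment",
                                               read_gmt(config$gmt)) else NULL
  de_enrich <- NULL
  if (!is.null(collection)) {
    de_union <- unique(unlist(de_sets))
    de_enrich <- wrap("enrichment", suppressWarnings(
      enrich_de_proteins(de_union, collection, rownames(lmat$values))))
    save_tsv(de_enrich, "de_enrichment.tsv")
    log <- stage_msg(log, "enrichment", "%d sets tested, %d at p <= %.3g",
                     nrow(de_enrich),
                     sum(de_enrich$p_value <= config$enrich_alpha),
                     config$enrich_alpha)
  }

  cvf <- wrap("cv_filter", cv_filter(fl$matrix, min_cv = config$min_cv))
  log <- stage_msg(log, "cv_filter", "%d -> %d proteins",
                   cvf$report$n_input, cvf$report$n_output)
  net_mat <- wrap("network", log2_transform(cvf$matrix))

  w <- wrap("network", pairwise_abs_pearson(net_mat))
  z <- wrap("network", suppressWarnings(
    permutation_zscores(net_mat, n_perm = config$n_perm,
                        seed = stream_seed(config$seed, "stage_network"))))
  network <- wrap("network", threshold_network(
    w, z, z_min = config$z_min, w_min = config$w_min,
    provenance = list(n_perm = config$n_perm, seed = config$seed)))
  rm(w, z)
  if (!is.null(outdir))
    write_edge_list(network, file.path(outdir, "coexpression_network.tsv"))
  log <- stage_msg(log, "network", "%d nodes, %d edges",
                   length(network$nodes), nrow(network$edges))

  downstream <- analyze_network(network, config, lmat, collection, log)
  log <- downstream$log

  report <- c(list(
    thresholds = config[c("min_count", "min_cv", "p_max", "lfc_min",
                          "n_perm", "z_min", "w_min", "module_min_size",
                          "reversal_alpha", "enrich_alpha",
                          "knowledge_min_score")],
    seed = config$seed,
    filter_low_abundance = fl$report,
    filter_cv = cvf$report,
    prior = list(d0 = mfit$d0, s02 = mfit$s02),
    de_counts = lengths(de_sets),
    de_union = sort(unique(unlist(de_sets))),
    restored = sort(restored),
    network = list(n_nodes = length(network$nodes),
                   n_edges = nrow(network$edges))
  ), downstream$report, list(log = log))
  report$contrasts <- contrasts
  report$de_enrichment <- de_enrich
  if (!is.null(outdir)) {
    slim <- report
    slim$contrasts <- NULL
    slim$de_enrichment <- NULL
    write_json_report(slim, file.path(outdir, "report.json"))
  }
  class(report) <- "RunReport"
  report
}

# community detection, reversal tests, enrichment and knowledge comparison
# on an already-thresholded network; shared by run_pipeline and
# run_from_network. `lmat` (log2 AbundanceMatrix) may be NULL when fold
# changes are unavailable.
analyze_network <- function(network, config, lmat = NULL, collection = NULL,
                            log = character()) {
  report <- list()
  if (nrow(network$edges)) {
    modules <- girvan_newman(network)
    mods <- filter_modules(modules, min_size = config$module_min_size)
    log <- stage_msg(log, "community",
                     "%d communities (Q = %.4f), %d with >= %d members",
                     modules$n_communities, modules$modularity,
                     nrow(mods), config$module_min_size)
  } else {
    modules <- NULL
    mods <- filter_modules(structure(list(
      membership = integer(), sizes = integer()), class = "ModuleSet"),
      min_size = config$module_min_size)
    log <- stage_msg(log, "community", "empty network; no modules")
  }
  report$modules <- list(
    n_communities = if (is.null(modules)) 0L else modules$n_communities,
    modularity = if (is.null(modules)) NA else modules$modularity,
    n_min_size = nrow(mods),
    sizes = mods$size
  )
  report$module_table <- mods

  if (!is.null(lmat) && nrow(mods)) {
    lfc_a <- replicate_wise_lfc(lmat, "O19_vs_O1")
    lfc_b <- replicate_wise_lfc(lmat, "O19_vs_O1CyA")
    rev_rows <- lapply(seq_len(nrow(mods)), function(i) {
      members <- strsplit(mods$members[i], ",", fixed = TRUE)[[1]]
      rt <- module_reversal_test(members, lfc_a, lfc_b,
                                 alpha = config$reversal_alpha)
      data.frame(module_id = mods$module_id[i], size = mods$size[i],
                 p_value = rt$p_value, mean_diff = rt$mean_diff,
                 flag = rt$flag, stringsAsFactors = FALSE)
    })
    rev_tab <- do.call(rbind, rev_rows)
    report$reversal <- rev_tab
    log <- stage_msg(log, "reversal", "%d of %d modules flagged at p <= %.3g",
                     sum(rev_tab$flag), nrow(rev_tab), config$reversal_alpha)
    if (!is.null(config$outdir))
      write.table(rev_tab, file.path(config$outdir, "module_reversal.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(collection) && !is.null(modules)) {
    universe <- if (!is.null(lmat)) rownames(lmat$values) else
      names(modules$membership)
    me <- suppressWarnings(
      module_enrichment(modules, collection, universe,
                        min_size = config$module_min_size,
                        alpha = config$enrich_alpha))
    report$module_enrichment <- me
    if (!is.null(config$outdir))
      write.table(me, file.path(config$outdir, "module_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$knowledge_edges) && !is.null(config$pathway_genes)) {
    ktab <- read.delim(config$knowledge_edges, stringsAsFactors = FALSE)
    genes <- readLines(config$pathway_genes)
    genes <- genes[nzchar(genes)]
    knet <- suppressWarnings(
      build_knowledge_network(ktab, genes,
                              min_score = config$knowledge_min_score))
    coex_nodes <- map_to_genes(network$nodes, config$id_map)
    shared <- overlap_nodes(coex_nodes, knet)
    hubs <- if (length(knet$nodes)) degree_ranking(knet, top_n = 20) else NULL
    report$knowledge <- list(
      n_nodes = length(knet$nodes), n_edges = nrow(knet$edges),
      n_overlap = length(shared), overlap = shared,
      top_hubs = if (is.null(hubs)) NULL else hubs$hubs,
      median_degree = if (is.null(hubs)) NA else hubs$median_degree
    )
    log <- stage_msg(log, "knowledge", "%d nodes, %d edges, %d shared nodes",
                     length(knet$nodes), nrow(knet$edges), length(shared))
  }
  if (length(network$nodes)) {
    dr <- degree_ranking(network, top_n = 20)
    report$coexpression_hubs <- dr$hubs
    report$coexpression_median_degree <- dr$median_degree
    if (!is.null(config$outdir))
      write.table(dr$histogram,
                  file.path(config$outdir, "degree_histogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, log = log)
}

# translate protein ids to gene symbols via an optional 2-column map file
map_to_genes <- function(ids, id_map_path) {
  if (is.null(id_map_path)) return(toupper(ids))
  map <- read.delim(id_map_path, header = TRUE, stringsAsFactors = FALSE)
  hit <- match(ids, map[[1]])
  dropped <- sum(is.na(hit))
  if (dropped) message(dropped, " protein id(s) without a gene mapping dropped")
  toupper(map[[2]][hit[!is.na(hit)]])
}

#' Run the network-stage pipeline from an edge list
#'
#' Entry point downstream of network inference: reads an already
#' thresholded edge list, then runs community detection, module filtering
#' and (when a knowledge network is configured) the node-overlap
#' comparison. Enables analysis of an externally supplied co-expression
#' network without raw abundances.
#'
#' @param config A `PipelineConfig`.
#' @param edge_list_path Path to the network edge list.
#' @return A `RunReport` list (network and module sections only).
#' @export
run_from_network <- function(config, edge_list_path) {
  stopifnot(inherits(config, "PipelineConfig"))
  edges <- read_edge_list(edge_list_path)
  if (!nrow(edges)) stop("stage 'input' failed: empty network")
  network <- as_weighted_network(edges, provenance = list(source = "file"))
  log <- stage_msg(character(), "input", "%d nodes, %d edges",
                   length(network$nodes), nrow(network$edges))
  downstream <- analyze_network(network, config, lmat = NULL,
                                collection = NULL, log = log)
  report <- c(list(
    thresholds = config[c("module_min_size", "reversal_alpha")],
    network = list(n_nodes = length(network$nodes),
                   n_edges = nrow(network$edges))
  ), downstream$report, list(log = downstream$log))
  if (!is.null(config$outdir)) {
    if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
    write_json_report(report, file.path(config$outdir, "report.json"))
  }
  class(report) <- "RunReport"
  report
}
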