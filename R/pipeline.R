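# End-to-end orchestration: (optional) simulate -> scan -> cluster properties
# and partnerships -> subclass co-occurrence -> composition grouping, with
# TSV/JSON exports and a reproducibility manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export clusters and membership as TSV
#'
#' Writes `clusters.tsv` (one row per cluster) and `membership.tsv`
#' (`cluster_id`, `cell_id`, sorted), both byte-deterministic for a fixed
#' input.
#'
#' @param clusters a `neuron_clusters` object.
#' @param dir output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_clusters <- function(clusters, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- write_tsv(clusters$clusters, file.path(dir, "clusters.tsv"))
  p2 <- write_tsv(clusters$membership, file.path(dir, "membership.tsv"))
  invisible(c(p1, p2))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) config <- yaml::read_yaml(config)
    else config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

config_to_analysis <- function(config, seed) {
  base <- if (!is.null(config$preset)) preset(config$preset)
          else analysis_config()
  analysis_config(
    window_size = config$window_size %||% base$window_size,
    step = config$step %||% base$step,
    n_perm = config$n_perm %||% base$n_perm,
    alpha = config$alpha %||% base$alpha,
    seed = seed,
    stratum = config$stratum %||% base$stratum,
    min_window_n = config$min_window_n %||% base$min_window_n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_stage <- function(sim, seed) {
  cfg <- scene_config(width = sim$width, height = sim$height,
                      lambda = sim$lambda %||% 500,
                      p_inh = sim$p_inh %||% 0.15,
                      n_layers = sim$n_layers %||% 1L,
                      regions = sim$regions,
                      section_id = sim$section_id %||% "S1",
                      seed = seed)
  cells <- generate_background(cfg)
  truth <- NULL
  if (!is.null(sim$planted)) {
    discs <- lapply(sim$planted, function(p) {
      planted_cluster(center = as.numeric(p$center), radius = p$radius,
                      class = p$class %||% "inhibitory",
                      fraction = p$fraction %||% 0.5,
                      density_mult = p$density_mult %||% 1)
    })
    res <- plant_clusters(cells, discs, cfg, seed = derive_seed(seed, 1L))
    cells <- res$cells
    truth <- res$truth
  }
  list(cells = cells, truth = truth, scene = cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - simulate (optional), scan, cluster
#' properties and partnerships, subclass co-occurrence, composition
#' grouping - and writes all exports plus a manifest (config snapshot, seed,
#' input digests, output inventory) into the output directory. One global
#' seed fans out to deterministic per-stage child seeds, so a fixed config
#' reproduces every output byte for byte.
#'
#' @param config a list, or a path to a YAML/JSON file, with entries:
#'   `out` (output directory); either `simulate` (scene description: `width`,
#'   `height`, `lambda`, `p_inh`, `n_layers`, optional `planted` disc list)
#'   or `cells` (path to a cell-table TSV); optional `annotation` (path to a
#'   region-annotation table); optional `preset`, `window_size`, `step`,
#'   `n_perm`, `alpha`, `stratum`; optional `cooccurrence` flags
#'   (`n_perm`, `meta_n_rep`); optional `compose` flags (`k`).
#' @param seed global integer seed (overrides `config$seed`).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, seed = NULL) {
  config <- read_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- config$out %||% stop("config$out (output directory) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)

  # --- stage 1: obtain cells -------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_stage(config$simulate, derive_seed(seed, 101L))
    cells <- sim$cells
    truth <- sim$truth
    write_cell_table(cells, file.path(out_dir, "cells.tsv"))
    if (!is.null(truth)) {
      jsonlite::write_json(
        list(planted = lapply(truth$planted, unclass),
             membership = truth$membership),
        file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    }
  } else if (!is.null(config$cells)) {
    cells <- read_cell_table(config$cells)
    inputs <- c(inputs, config$cells)
  } else {
    stop("config must provide either 'simulate' or 'cells'")
  }
  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- read_region_annotation(config$annotation)
    inputs <- c(inputs, config$annotation)
  }

  # --- stage 2: scan ---------------------------------------------------------
  acfg <- config_to_analysis(config, derive_seed(seed, 102L))
  clusters <- detect_clusters(cells, acfg)
  write_clusters(clusters, out_dir)

  # --- stage 3: properties and partnerships ---------------------------------
  summaries <- cluster_summaries(clusters, cells)
  write_tsv(summaries, file.path(out_dir, "cluster_summaries.tsv"))
  partners <- find_partners(clusters)
  write_tsv(partners$pairs, file.path(out_dir, "partner_pairs.tsv"))
  nearest <- nearest_opposite_cluster(clusters, cells)
  coupling <- coupling_stats(summaries, partners, nearest)
  coverage <- coverage_stats(clusters, cells)
  balance <- if (nrow(clusters$clusters) > 0L)
    class_balance_test(clusters, cells) else NULL

  # --- stage 4: co-occurrence ------------------------------------------------
  cooc_cfg <- config$cooccurrence %||% list()
  enr <- subclass_enrichment(clusters, cells,
                             n_perm = cooc_cfg$n_perm %||% 1000,
                             seed = derive_seed(seed, 104L),
                             alpha = acfg$alpha, stratum = acfg$stratum)
  write_tsv(enr, file.path(out_dir, "subclass_enrichment.tsv"))
  combos <- if (nrow(enr) > 0L) classify_combinations(enr, clusters) else NULL
  meta <- NULL
  if (!is.null(cooc_cfg$meta_n_rep) && nrow(clusters$clusters) > 0L) {
    meta <- meta_permutation(clusters, cells,
                             n_perm = cooc_cfg$n_perm %||% 1000,
                             n_rep = cooc_cfg$meta_n_rep,
                             seed = derive_seed(seed, 105L),
                             alpha = acfg$alpha, stratum = acfg$stratum)
  }

  # --- stage 5: composition --------------------------------------------------
  compose <- NULL
  comp_cfg <- config$compose %||% list()
  if (nrow(clusters$clusters) >= 2L) {
    comp <- composition_vectors(clusters, cells)
    k <- min(comp_cfg$k %||% 5L, nrow(comp$presence))
    groups <- hierarchical_groups(comp$presence, k = k)
    fenr <- if (!is.null(annotation))
      functional_enrichment(groups, summaries, annotation) else NULL
    gsum <- group_system_summary(groups, summaries, comp, fenr)
    write_tsv(groups, file.path(out_dir, "composition_groups.tsv"))
    write_tsv(as.data.frame(gsum$presence_freq),
              file.path(out_dir, "group_presence_freq.tsv"))
    if (!is.null(fenr)) write_tsv(fenr, file.path(out_dir, "functional_enrichment.tsv"))
    hier <- if (!is.null(annotation))
      hierarchy_correlation(summaries, annotation) else NULL
    compose <- list(composition = comp, groups = groups, summary = gsum,
                    enrichment = fenr, hierarchy = hier)
  }

  # --- stats + manifest ------------------------------------------------------
  stats_report <- list(
    n_cells = nrow(cells),
    n_clusters = nrow(clusters$clusters),
    n_clusters_exc = sum(clusters$clusters$type == "excitatory"),
    n_clusters_inh = sum(clusters$clusters$type == "inhibitory"),
    coverage = coverage,
    class_balance = balance,
    coupling = coupling,
    cooccurrence = if (!is.null(combos)) combos$summary else NULL,
    meta_permutation = if (!is.null(meta))
      list(observed = meta$observed, p = meta$p) else NULL)
  jsonlite::write_json(stats_report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  outputs <- sort(list.files(out_dir))
  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "out")],
    analysis_config = unclass(acfg),
    input_digests = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list(),
    outputs = setdiff(outputs, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(cells = cells, truth = truth, clusters = clusters,
                 summaries = summaries, partners = partners,
                 nearest = nearest, coupling = coupling, coverage = coverage,
                 balance = balance, enrichment = enr, combinations = combos,
                 meta = meta, compose = compose, config = acfg))
}
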