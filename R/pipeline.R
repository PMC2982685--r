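# End-to-end orchestration: assembly -> per-region edge scoring ->
# crosstalk + clustering -> dysregulation ranking -> enrichment, with every
# stage's tables written as TSV and a reproducibility manifest.

#' Pipeline configuration
#'
#' Exactly one input mode must be given: `simulation` (a
#' [simulation_config()], inputs are generated and written alongside the
#' results) or `paths` (a named list with `gmt`, `edges`, `expression`,
#' `samples`, `annotations` TSV/GMT files).
#'
#' @param simulation optional [simulation_config()].
#' @param paths optional named list of input paths.
#' @param focal_id focal pathway id (default: the simulation's focal
#'   pathway; required in real-data mode).
#' @param min_votes database votes required to keep an interaction.
#' @param n_perm permutation count for both resampling tests.
#' @param seed master seed for the permutation streams.
#' @param strict strict `>` exceedance (default) vs `>=`.
#' @param smoothed add-one smoothing of permutation p-values.
#' @param p_floor smallest admissible p-value in edge scoring.
#' @param linkage,min_cluster_size,cut_height clustering parameters
#'   (see [cluster_pathways()]).
#' @param top_n ranked pathways reported per region.
#' @param top_t enriched terms reported per pathway.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL, focal_id = NULL,
                            min_votes = 3L, n_perm = 10000L, seed = 1L,
                            strict = TRUE, smoothed = FALSE, p_floor = 1e-300,
                            linkage = "average", min_cluster_size = 3L,
                            cut_height = 0.5, top_n = 5L, top_t = 3L,
                            out_dir = tempfile("crosstalk_run_"),
                            quiet = FALSE) {
  if (is.null(simulation) == is.null(paths)) {
    abort_stage("config", "give exactly one of 'simulation' or 'paths'")
  }
  if (!is.null(paths)) {
    need <- c("gmt", "edges", "expression", "samples", "annotations")
    if (!all(need %in% names(paths))) {
      abort_stage("config", paste("paths needs entries:", paste(need, collapse = ", ")))
    }
    if (is.null(focal_id)) {
      abort_stage("config", "real-data mode requires 'focal_id'")
    }
  }
  structure(list(simulation = simulation, paths = paths, focal_id = focal_id,
                 min_votes = check_count(min_votes, "min_votes", 1L),
                 n_perm = check_count(n_perm, "n_perm", 1L),
                 seed = as.integer(seed), strict = isTRUE(strict),
                 smoothed = isTRUE(smoothed), p_floor = p_floor,
                 linkage = linkage,
                 min_cluster_size = check_count(min_cluster_size,
                                                "min_cluster_size", 1L),
                 cut_height = cut_height, top_n = top_n, top_t = top_t,
                 out_dir = out_dir, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

# cbind a region label that also works for zero-row tables
add_region <- function(reg, df) {
  if (nrow(df)) cbind(region = reg, df) else cbind(region = character(), df)
}

stage_log <- function(config, stage, fmt, ...) {
  if (!config$quiet) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the full crosstalk pipeline
#'
#' Executes network assembly, per-region edge scoring, pathway-pathway
#' crosstalk with clustering, dysregulation ranking, and term enrichment.
#' All result tables are written as TSV under `config$out_dir`, networks as
#' GraphML, dendrograms as Newick, and a JSON manifest captures the
#' configuration and input hashes so a run can be reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `network`,
#'   `mapped`, `frame`, per-region `scores`, `crosstalk`, `clusters`,
#'   `dysregulation`, `ranking`, plus `enrichment` and the `out_dir`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ----
  if (!is.null(config$simulation)) {
    stage_log(config, "inputs", "simulating inputs (seed %d)",
              config$simulation$seed)
    sim <- simulate_crosstalk_data(config$simulation)
    input_dir <- file.path(config$out_dir, "inputs")
    write_simulation(sim, input_dir)
    pathways <- sim$pathways
    databases <- sim$databases
    expression <- lapply(sim$expression, function(x) {
      list(control = collapse_probes(x$control),
           disease = collapse_probes(x$disease))
    })
    annotations <- sim$annotations
    focal_id <- if (is.null(config$focal_id)) attr(pathways, "focal") else config$focal_id
    input_files <- list.files(input_dir, full.names = TRUE)
  } else {
    stage_log(config, "inputs", "reading inputs")
    pathways <- read_gmt(config$paths$gmt)
    databases <- read_edge_lists(config$paths$edges)
    expression <- read_expression(config$paths$expression, config$paths$samples)
    annotations <- read_annotations(config$paths$annotations)
    focal_id <- config$focal_id
    input_files <- unlist(config$paths, use.names = FALSE)
  }
  if (!focal_id %in% names(pathways)) {
    abort_stage("inputs", sprintf("focal pathway '%s' not found in collection",
                                  focal_id))
  }

  # ---- assembly ----
  network <- build_ensemble_network(databases, min_votes = config$min_votes)
  stage_log(config, "assembly", "ensemble network: %d nodes, %d edges",
            length(network$nodes), nrow(network$edges))
  neighbors <- find_neighbor_pathways(focal_id, pathways)
  analysis_set <- c(pathways[focal_id], neighbors)
  stage_log(config, "assembly", "focal pathway %s with %d neighbor pathways",
            focal_id, length(neighbors))
  expressed <- Reduce(intersect, lapply(expression, function(x) {
    intersect(rownames(x$control), rownames(x$disease))
  }))
  mapped <- lapply(analysis_set, map_pathway, network = network,
                   expressed_genes = expressed)
  empty <- vapply(mapped, `[[`, TRUE, "empty")
  if (any(empty)) {
    stage_log(config, "assembly", "dropping %d empty mapped pathway(s): %s",
              sum(empty), paste(names(mapped)[empty], collapse = ", "))
  }
  mapped <- mapped[!empty]
  if (length(mapped) < 2L) {
    abort_stage("assembly", "fewer than two non-empty mapped pathways")
  }
  pgraph <- build_pathway_graph(mapped)
  frame <- union_edge_frame(mapped)
  stage_log(config, "assembly", "network of pathways: %d pathways, %d frame edges",
            length(mapped), nrow(frame))

  mp_tab <- do.call(rbind, lapply(mapped, function(mp) {
    data.frame(pathway = mp$id, n_raw_genes = mp$n_raw_genes,
               n_nodes = length(mp$genes), n_edges = nrow(mp$edges),
               n_isolated_dropped = length(mp$dropped_isolated),
               description = mp$name, stringsAsFactors = FALSE)
  }))
  write_result_table(mp_tab, file.path(config$out_dir, "mapped_pathways.tsv"))
  utils::write.table(network$edges, file.path(config$out_dir, "network_ensemble.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_graphml(network, file.path(config$out_dir, "network_ensemble.graphml"))
  utils::write.table(pgraph$edges, file.path(config$out_dir, "pathway_graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_graphml(pgraph, file.path(config$out_dir, "pathway_graph.graphml"))

  # ---- per-region analysis ----
  ids <- sort(vapply(mapped, `[[`, "", "id"))
  universe <- sort(unique(unlist(lapply(mapped, `[[`, "genes"))))
  results <- list()
  for (reg in names(expression)) {
    t_reg <- Sys.time()
    ex <- expression[[reg]]
    scores <- score_edges(frame, ex$control, ex$disease, p_floor = config$p_floor)
    sc_out <- add_region(reg, scores)
    write_result_table(sc_out,
                       file.path(config$out_dir, sprintf("edge_scores_%s.tsv", reg)),
                       p_cols = "combined_p")

    ct <- crosstalk_table(mapped, scores, frame, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, paste0("crosstalk:", reg)),
                          strict = config$strict, smoothed = config$smoothed)
    write_result_table(add_region(reg, ct),
                       file.path(config$out_dir, sprintf("crosstalk_%s.tsv", reg)))
    D <- distance_matrix(ct, ids)
    utils::write.table(data.frame(pathway = rownames(D), D, check.names = FALSE),
                       file.path(config$out_dir, sprintf("distance_%s.tsv", reg)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clusters <- cluster_pathways(D, linkage = config$linkage,
                                 min_cluster_size = config$min_cluster_size,
                                 cut_height = config$cut_height)
    write_result_table(add_region(reg, clusters),
                       file.path(config$out_dir, sprintf("clusters_%s.tsv", reg)))
    export_newick(clusters, file.path(config$out_dir,
                                      sprintf("dendrogram_%s.nwk", reg)))
    # focal-cluster report: members of the focal pathway's cluster with
    # their crosstalk significance against the focal pathway
    members <- focal_cluster_members(clusters, focal_id)
    fc <- ct[(ct$pathway_i == focal_id & ct$pathway_j %in% members) |
               (ct$pathway_j == focal_id & ct$pathway_i %in% members), , drop = FALSE]
    if (nrow(fc)) {
      fc$pathway <- ifelse(fc$pathway_i == focal_id, fc$pathway_j, fc$pathway_i)
      fc <- merge(fc[c("pathway", "n_overlap_edges", "overlap_score", "p_value")],
                  mp_tab, by = "pathway")
      fc <- fc[order(fc$pathway),
               c("pathway", "n_raw_genes", "n_edges", "n_nodes",
                 "p_value", "n_overlap_edges", "overlap_score", "description")]
    } else {
      fc <- data.frame(pathway = character(), n_raw_genes = integer(),
                       n_edges = integer(), n_nodes = integer(),
                       p_value = numeric(), n_overlap_edges = integer(),
                       overlap_score = numeric(), description = character())
    }
    write_result_table(add_region(reg, fc),
                       file.path(config$out_dir, sprintf("focal_cluster_%s.tsv", reg)))

    dys <- dysregulation_table(mapped, scores, frame, n_perm = config$n_perm,
                               seed = derive_seed(config$seed,
                                                  paste0("dysregulation:", reg)),
                               strict = config$strict, smoothed = config$smoothed)
    write_result_table(add_region(reg, dys),
                       file.path(config$out_dir, sprintf("dysregulation_%s.tsv", reg)))
    ranking <- rank_pathways(dys, top_n = config$top_n)
    write_result_table(add_region(reg, ranking),
                       file.path(config$out_dir, sprintf("ranking_%s.tsv", reg)))
    results[[reg]] <- list(scores = scores, crosstalk = ct, distance = D,
                           clusters = clusters, dysregulation = dys,
                           ranking = ranking)
    stage_log(config, "region", "%s done in %.1f s", reg,
              as.numeric(difftime(Sys.time(), t_reg, units = "secs")))
  }

  # ---- enrichment (annotation-based, region-independent) ----
  enr <- do.call(rbind, lapply(mapped, function(mp) {
    e <- enrich_pathway(mp$genes, annotations, universe, top_t = config$top_t)
    if (nrow(e)) cbind(pathway = mp$id, e) else NULL
  }))
  if (is.null(enr)) {
    enr <- data.frame(pathway = character(), term = character(),
                      term_name = character(), n = integer(), f = integer(),
                      m = integer(), k = integer(), p_value = numeric(),
                      p_adjust = numeric(), rank = integer())
  }
  enr <- enr[order(enr$pathway, enr$rank), , drop = FALSE]
  rownames(enr) <- NULL
  write_result_table(enr, file.path(config$out_dir, "enrichment.tsv"))

  # ---- manifest ----
  manifest <- list(
    package = "pathwaycrosstalk",
    version = as.character(utils::packageVersion("pathwaycrosstalk")),
    seed = config$seed,
    config = config_manifest(config),
    input_hashes = as.list(stats::setNames(unname(tools::md5sum(sort(input_files))),
                                           basename(sort(input_files)))),
    regions = names(expression),
    focal_id = focal_id,
    n_frame_edges = nrow(frame),
    n_pathways = length(mapped)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(config, "done", "pipeline finished in %.1f s -> %s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            config$out_dir)
  invisible(list(network = network, mapped = mapped, frame = frame,
                 pathway_graph = pgraph, regions = results,
                 enrichment = enr, focal_id = focal_id,
                 out_dir = config$out_dir))
}

config_manifest <- function(config) {
  keep <- setdiff(names(unclass(config)),
                  c("simulation", "paths", "quiet", "out_dir"))
  out <- unclass(config)[keep]
  out$mode <- if (is.null(config$simulation)) "files" else "simulation"
  if (!is.null(config$simulation)) out$simulation <- unclass(config$simulation)
  if (!is.null(config$paths)) out$paths <- config$paths
  out
}
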