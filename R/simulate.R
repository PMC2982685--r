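# Synthetic-data generator: interaction databases, pathway collections,
# two-condition regional expression with planted effects, and annotations.
# Every downstream stage of the pipeline can be exercised on its output.

REGION_NAMES <- c("EC", "HIP", "MTG", "PC", "SFG", "VCX")

#' Simulation configuration
#'
#' Describes the synthetic world the generator emits: a gene universe, five
#' overlapping interaction databases, a focal disease pathway plus neighbor
#' pathways that each share genes with it, per-region control/disease
#' expression with planted mean shifts and planted disease-only correlation,
#' and a term annotation table with one planted enriched term.
#'
#' @param n_genes size of the gene universe.
#' @param n_databases number of interaction databases to emit.
#' @param db_coverage probability that a true interaction appears in any one
#'   database.
#' @param spurious_rate per-database rate of false interactions, expressed as
#'   a fraction of the true-edge count.
#' @param edge_density background Erdos-Renyi edge probability over the gene
#'   universe.
#' @param within_pathway_density edge probability for gene pairs inside a
#'   pathway (pathway subgraphs are denser than background, as in curated
#'   pathway maps).
#' @param n_pathways number of pathways including the focal one.
#' @param pathway_size_range integer (min, max) gene counts per pathway.
#' @param focal_overlap_range integer (min, max) genes each neighbor pathway
#'   shares with the focal pathway.
#' @param n_regions number of regions (named EC, HIP, MTG, PC, SFG, VCX for
#'   the first six).
#' @param n_control,n_disease samples per condition per region (>= 3; the
#'   correlation test needs at least three pairs).
#' @param de_effect mean shift, in within-group SD units, planted on
#'   differentially expressed genes in disease samples.
#' @param coexpr_rho target disease-only correlation planted on selected
#'   interactions.
#' @param planted_pathways ids of pathways carrying planted signal
#'   (default the focal pathway, "P01").
#' @param n_terms number of annotation terms.
#' @param planted_term_enrichment fraction of focal-pathway genes annotated
#'   with the planted term.
#' @param annotation_rate background probability that a gene carries a given
#'   background term.
#' @param planted_term_background background annotation rate of the planted
#'   term outside the focal pathway.
#' @param probes_per_gene probes emitted per gene (> 1 produces duplicated
#'   gene rows that must be averaged downstream).
#' @param probe_noise_sd measurement noise SD added per probe when
#'   `probes_per_gene > 1`.
#' @param seed master RNG seed; every stage derives its own stream from it
#'   via [derive_seed()].
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 300L,
                              n_databases = 5L,
                              db_coverage = 0.7,
                              spurious_rate = 0.05,
                              edge_density = 0.01,
                              within_pathway_density = 0.35,
                              n_pathways = 12L,
                              pathway_size_range = c(10L, 30L),
                              focal_overlap_range = c(1L, 5L),
                              n_regions = 6L,
                              n_control = 15L,
                              n_disease = 15L,
                              de_effect = 1.5,
                              coexpr_rho = 0.6,
                              planted_pathways = "P01",
                              n_terms = 50L,
                              planted_term_enrichment = 0.8,
                              annotation_rate = 0.05,
                              planted_term_background = 0.01,
                              probes_per_gene = 1L,
                              probe_noise_sd = 0.2,
                              seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", 2L),
    n_databases = check_count(n_databases, "n_databases", 1L),
    db_coverage = check_probability(db_coverage, "db_coverage"),
    spurious_rate = spurious_rate,
    edge_density = check_probability(edge_density, "edge_density"),
    within_pathway_density = check_probability(within_pathway_density,
                                               "within_pathway_density"),
    n_pathways = check_count(n_pathways, "n_pathways", 1L),
    pathway_size_range = as.integer(pathway_size_range),
    focal_overlap_range = as.integer(focal_overlap_range),
    n_regions = check_count(n_regions, "n_regions", 1L),
    n_control = check_count(n_control, "n_control", 3L),
    n_disease = check_count(n_disease, "n_disease", 3L),
    de_effect = de_effect,
    coexpr_rho = check_probability(coexpr_rho, "coexpr_rho"),
    planted_pathways = as.character(planted_pathways),
    n_terms = check_count(n_terms, "n_terms", 1L),
    planted_term_enrichment = check_probability(planted_term_enrichment,
                                                "planted_term_enrichment"),
    annotation_rate = check_probability(annotation_rate, "annotation_rate"),
    planted_term_background = check_probability(planted_term_background,
                                                "planted_term_background"),
    probes_per_gene = check_count(probes_per_gene, "probes_per_gene", 1L),
    probe_noise_sd = probe_noise_sd,
    seed = as.integer(seed)
  )
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] < 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2]) {
    abort_stage("config", "'pathway_size_range' must be (min >= 2, max >= min)")
  }
  if (length(cfg$focal_overlap_range) != 2L ||
      cfg$focal_overlap_range[1] < 1L ||
      cfg$focal_overlap_range[1] > cfg$focal_overlap_range[2]) {
    abort_stage("config", "'focal_overlap_range' must be (min >= 1, max >= min)")
  }
  if (!is.numeric(cfg$spurious_rate) || cfg$spurious_rate < 0) {
    abort_stage("config", "'spurious_rate' must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

region_names <- function(n) {
  if (n <= length(REGION_NAMES)) REGION_NAMES[seq_len(n)]
  else c(REGION_NAMES, sprintf("R%02d", seq_len(n - length(REGION_NAMES)) +
                                 length(REGION_NAMES)))
}

gene_universe <- function(config) {
  sprintf("g%04d", seq_len(config$n_genes))
}

#' Simulate a pathway collection
#'
#' Draws `n_pathways` gene sets from the universe. The first pathway ("P01")
#' is the focal disease pathway; every other pathway is constructed to share
#' between `focal_overlap_range[1]` and `focal_overlap_range[2]` genes with
#' it, so all non-focal pathways are neighbors of the focal pathway by the
#' shared-gene definition.
#'
#' @param config a [simulation_config()].
#' @param universe character vector of gene ids (default derived from
#'   `config`).
#' @param seed RNG seed (default derived from `config$seed`).
#' @return named list of pathways, each `list(id, name, genes)`, with
#'   attribute `focal` naming the focal pathway id.
#' @export
simulate_pathways <- function(config, universe = gene_universe(config),
                              seed = derive_seed(config$seed, "pathways")) {
  szr <- config$pathway_size_range
  ovr <- config$focal_overlap_range
  if (szr[2] > length(universe)) {
    abort_stage("config", "gene universe smaller than max pathway size")
  }
  with_seed(seed, {
    sizes <- sample(seq(szr[1], szr[2]), config$n_pathways, replace = TRUE)
    focal_genes <- sort(sample(universe, sizes[1]))
    paths <- vector("list", config$n_pathways)
    ids <- sprintf("P%02d", seq_len(config$n_pathways))
    paths[[1]] <- list(id = ids[1], name = "focal disease pathway",
                       genes = focal_genes)
    non_focal <- setdiff(universe, focal_genes)
    for (i in seq_len(config$n_pathways)[-1]) {
      ov <- sample(seq(ovr[1], min(ovr[2], length(focal_genes), sizes[i])), 1L)
      n_rest <- sizes[i] - ov
      if (n_rest > length(non_focal)) {
        abort_stage("config", "gene universe too small for requested pathway sizes")
      }
      genes <- sort(c(sample(focal_genes, ov),
                      if (n_rest > 0) sample(non_focal, n_rest)))
      paths[[i]] <- list(id = ids[i], name = sprintf("neighbor pathway %02d", i),
                         genes = genes)
    }
    names(paths) <- ids
    attr(paths, "focal") <- ids[1]
    class(paths) <- "pathway_collection"
    paths
  })
}

all_pairs <- function(genes) {
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  idx <- utils::combn(sort(genes), 2L)
  data.frame(gene_a = idx[1, ], gene_b = idx[2, ], stringsAsFactors = FALSE)
}

#' Simulate interaction databases
#'
#' Draws a true undirected interaction set over the gene universe --
#' background Erdos-Renyi edges plus denser subgraphs inside each pathway --
#' then emits `n_databases` noisy views of it: each database contains every
#' true edge independently with probability `db_coverage` and adds spurious
#' edges (drawn uniformly from non-edges) at `spurious_rate` times the
#' true-edge count.
#'
#' @param config a [simulation_config()].
#' @param pathways optional pathway collection used to densify within-pathway
#'   interactions; when `NULL` only background edges are drawn.
#' @param seed RNG seed (default derived from `config$seed`).
#' @return list with `databases` (list of canonical edge data.frames) and
#'   `true_edges` (canonical edge data.frame).
#' @export
simulate_interactome <- function(config, pathways = NULL,
                                 seed = derive_seed(config$seed, "interactome")) {
  universe <- gene_universe(config)
  with_seed(seed, {
    n <- length(universe)
    n_pairs <- n * (n - 1) / 2
    n_bg <- stats::rbinom(1L, n_pairs, config$edge_density)
    # sample background pairs by index without materializing all pairs
    bg_idx <- sample.int(n_pairs, n_bg)
    bg <- pair_from_index(bg_idx, universe)
    within <- list()
    if (!is.null(pathways)) {
      within <- lapply(pathways, function(p) {
        pp <- all_pairs(p$genes)
        pp[stats::runif(nrow(pp)) < config$within_pathway_density, , drop = FALSE]
      })
    }
    true_edges <- canonical_edges(do.call(rbind, c(list(bg), within)))
    n_true <- nrow(true_edges)
    true_keys <- edge_key(true_edges)
    n_spur <- round(config$spurious_rate * n_true)
    dbs <- lapply(seq_len(config$n_databases), function(d) {
      keep <- stats::runif(n_true) < config$db_coverage
      db <- true_edges[keep, , drop = FALSE]
      if (n_spur > 0) {
        spur <- sample_non_edges(universe, true_keys, n_spur)
        db <- rbind(db, spur)
      }
      canonical_edges(db)
    })
    names(dbs) <- sprintf("db%d", seq_along(dbs))
    list(databases = dbs, true_edges = true_edges)
  })
}

# Map linear indices of the upper triangle (column-major over sorted gene
# pairs i < j) back to gene pairs.
pair_from_index <- function(idx, universe) {
  n <- length(universe)
  # row-major enumeration: pair (i, j), i < j, index = (i-1)*n - i*(i+1)/2 + j
  i <- findInterval(idx - 1, cumsum((n - 1):1), left.open = FALSE) + 1L
  offset <- c(0, cumsum((n - 1):1))[i]
  j <- idx - offset + i
  canonical_edges(data.frame(gene_a = universe[i], gene_b = universe[j],
                             stringsAsFactors = FALSE))
}

sample_non_edges <- function(universe, true_keys, n_spur) {
  out <- NULL
  guard <- 0L
  while ((is.null(out) || nrow(out) < n_spur) && guard < 50L) {
    cand <- data.frame(gene_a = sample(universe, 2L * n_spur, replace = TRUE),
                       gene_b = sample(universe, 2L * n_spur, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- canonical_edges(cand)
    cand <- cand[!(edge_key(cand) %in% true_keys), , drop = FALSE]
    out <- canonical_edges(rbind(out, cand))
    guard <- guard + 1L
  }
  out[seq_len(min(n_spur, nrow(out))), , drop = FALSE]
}

#' Choose planted signal targets
#'
#' Differentially expressed genes are the union of the planted pathways'
#' genes. Planted correlated interactions are a greedy gene-disjoint matching
#' among true edges internal to the planted pathways, so each gene enters at
#' most one latent correlation factor and the planted pairwise correlation
#' equals `coexpr_rho` exactly in population.
#'
#' @param config a [simulation_config()].
#' @param pathways pathway collection.
#' @param true_edges canonical true edge table.
#' @return list with `de_genes` and `correlated_edges`.
#' @export
plant_targets <- function(config, pathways, true_edges) {
  planted <- intersect(config$planted_pathways, names(pathways))
  de_genes <- sort(unique(unlist(lapply(pathways[planted], `[[`, "genes"))))
  internal <- true_edges[true_edges$gene_a %in% de_genes &
                           true_edges$gene_b %in% de_genes, , drop = FALSE]
  used <- character()
  keep <- logical(nrow(internal))
  for (r in seq_len(nrow(internal))) {
    a <- internal$gene_a[r]; b <- internal$gene_b[r]
    if (!(a %in% used) && !(b %in% used)) {
      keep[r] <- TRUE
      used <- c(used, a, b)
    }
  }
  list(de_genes = de_genes,
       correlated_edges = internal[keep, , drop = FALSE])
}

#' Simulate per-region two-condition expression
#'
#' Baseline expression is i.i.d. standard normal per gene and sample (the
#' continuous, roughly Gaussian scale of normalized log-intensity data).
#' Disease samples get a `+de_effect` mean shift on planted genes; planted
#' correlated gene pairs share a latent factor `z` in disease samples only:
#' `x = sqrt(rho) z + sqrt(1 - rho) eps`, giving population correlation
#' `rho` between the pair. Regions carry independent noise. With
#' `probes_per_gene > 1` each gene is emitted as several probe rows (gene
#' value plus probe noise) that downstream readers must average.
#'
#' @param config a [simulation_config()].
#' @param truth list with `de_genes` and `correlated_edges` (see
#'   [plant_targets()]); pass empty sets for a global-null simulation.
#' @param seed RNG seed (default derived from `config$seed`).
#' @return named list over regions; each element has `control` and `disease`
#'   numeric matrices (rows = probes, with gene ids as row names; duplicated
#'   row names when `probes_per_gene > 1`).
#' @export
simulate_expression <- function(config, truth = list(de_genes = character(),
                                                     correlated_edges = NULL),
                                seed = derive_seed(config$seed, "expression")) {
  genes <- gene_universe(config)
  regions <- region_names(config$n_regions)
  ce <- truth$correlated_edges
  if (is.null(ce)) ce <- data.frame(gene_a = character(), gene_b = character())
  out <- lapply(regions, function(reg) {
    rseed <- derive_seed(seed, paste0("region:", reg))
    with_seed(rseed, {
      nG <- length(genes)
      ctrl <- matrix(stats::rnorm(nG * config$n_control), nrow = nG,
                     dimnames = list(genes, sprintf("%s_C%02d", reg,
                                                    seq_len(config$n_control))))
      dis <- matrix(stats::rnorm(nG * config$n_disease), nrow = nG,
                    dimnames = list(genes, sprintf("%s_D%02d", reg,
                                                   seq_len(config$n_disease))))
      rho <- config$coexpr_rho
      if (nrow(ce) > 0 && rho > 0) {
        for (r in seq_len(nrow(ce))) {
          z <- stats::rnorm(config$n_disease)
          for (g in c(ce$gene_a[r], ce$gene_b[r])) {
            dis[g, ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(config$n_disease)
          }
        }
      }
      if (length(truth$de_genes) > 0 && config$de_effect != 0) {
        dis[truth$de_genes, ] <- dis[truth$de_genes, ] + config$de_effect
      }
      if (config$probes_per_gene > 1L) {
        ctrl <- expand_probes(ctrl, config$probes_per_gene, config$probe_noise_sd)
        dis <- expand_probes(dis, config$probes_per_gene, config$probe_noise_sd)
      }
      list(control = ctrl, disease = dis)
    })
  })
  names(out) <- regions
  out
}

expand_probes <- function(mat, k, noise_sd) {
  idx <- rep(seq_len(nrow(mat)), each = k)
  out <- mat[idx, , drop = FALSE] +
    matrix(stats::rnorm(length(idx) * ncol(mat), sd = noise_sd),
           nrow = length(idx))
  rownames(out) <- rownames(mat)[idx]
  out
}

#' Simulate a term annotation table
#'
#' Background terms annotate genes uniformly at random at `annotation_rate`.
#' The planted term ("T01") annotates a `planted_term_enrichment` fraction of
#' the focal pathway's genes plus non-focal genes at
#' `planted_term_background`.
#'
#' @param config a [simulation_config()].
#' @param pathways pathway collection (the focal pathway anchors the planted
#'   term).
#' @param seed RNG seed (default derived from `config$seed`).
#' @return data.frame with columns `term`, `gene`, `term_name` and attribute
#'   `planted_term`.
#' @export
simulate_annotations <- function(config, pathways,
                                 seed = derive_seed(config$seed, "annotations")) {
  genes <- gene_universe(config)
  focal <- pathways[[attr(pathways, "focal")]]$genes
  with_seed(seed, {
    terms <- sprintf("T%02d", seq_len(config$n_terms))
    planted <- terms[1]
    n_hit <- round(config$planted_term_enrichment * length(focal))
    hit <- if (n_hit > 0) sample(focal, n_hit) else character()
    bg_pool <- setdiff(genes, focal)
    bg_hit <- bg_pool[stats::runif(length(bg_pool)) < config$planted_term_background]
    rows <- list(data.frame(term = planted, gene = c(hit, bg_hit),
                            stringsAsFactors = FALSE))
    for (t in terms[-1]) {
      tg <- genes[stats::runif(length(genes)) < config$annotation_rate]
      if (length(tg) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(term = t, gene = tg,
                                                stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    ann <- ann[order(ann$term, ann$gene), , drop = FALSE]
    ann$term_name <- ifelse(ann$term == planted, "planted enriched process",
                            paste("background process", ann$term))
    rownames(ann) <- NULL
    attr(ann, "planted_term") <- planted
    ann
  })
}

#' Simulate a complete pipeline input set
#'
#' Runs the generator stages in order -- pathways, interactome, planted
#' targets, per-region expression, annotations -- all seeded from
#' `config$seed`, and bundles the results with the ground truth needed by
#' tests.
#'
#' @param config a [simulation_config()].
#' @return object of class `crosstalk_simulation`: list with `config`,
#'   `pathways`, `databases`, `expression`, `annotations` and `truth`
#'   (true edges, planted DE genes, planted correlated edges, planted term).
#' @export
simulate_crosstalk_data <- function(config = simulation_config()) {
  pathways <- simulate_pathways(config)
  inter <- simulate_interactome(config, pathways)
  targets <- plant_targets(config, pathways, inter$true_edges)
  expression <- simulate_expression(config, targets)
  annotations <- simulate_annotations(config, pathways)
  structure(list(
    config = config,
    pathways = pathways,
    databases = inter$databases,
    expression = expression,
    annotations = annotations,
    truth = list(true_edges = inter$true_edges,
                 de_genes = targets$de_genes,
                 correlated_edges = targets$correlated_edges,
                 focal_id = attr(pathways, "focal"),
                 planted_term = attr(annotations, "planted_term"))
  ), class = "crosstalk_simulation")
}

#' @export
print.crosstalk_simulation <- function(x, ...) {
  cat(sprintf(paste0("crosstalk simulation: %d genes, %d pathways, ",
                     "%d databases, %d regions\n"),
              x$config$n_genes, length(x$pathways), length(x$databases),
              length(x$expression)))
  cat(sprintf("  true edges: %d; planted DE genes: %d; planted correlated edges: %d\n",
              nrow(x$truth$true_edges), length(x$truth$de_genes),
              nrow(x$truth$correlated_edges)))
  invisible(x)
}
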