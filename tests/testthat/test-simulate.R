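test_that("configuration invariants are enforced", {
  expect_error(simulation_config(db_coverage = 1.5), "probability")
  expect_error(simulation_config(n_control = 2), "n_control")
  expect_error(simulation_config(pathway_size_range = c(1, 5)),
               "pathway_size_range")
  expect_error(simulation_config(n_terms = 0), "n_terms")
  expect_s3_class(simulation_config(), "sim_config")
})

test_that("interactome databases honor degenerate coverage", {
  cfg1 <- simulation_config(n_genes = 60, db_coverage = 1, spurious_rate = 0,
                            n_pathways = 3, seed = 5)
  pws <- simulate_pathways(cfg1)
  res <- simulate_interactome(cfg1, pws)
  for (db in res$databases) {
    expect_identical(edge_key(db), edge_key(res$true_edges))
  }
  cfg0 <- simulation_config(n_genes = 60, db_coverage = 0, spurious_rate = 0,
                            n_pathways = 3, seed = 5)
  res0 <- simulate_interactome(cfg0, simulate_pathways(cfg0))
  expect_true(all(vapply(res0$databases, nrow, 1L) == 0L))
  # structural invariants: canonical orientation, no self-loops
  expect_true(all(res$true_edges$gene_a < res$true_edges$gene_b))
})

test_that("per-edge database votes match the binomial expectation", {
  cfg <- simulation_config(n_genes = 400, db_coverage = 0.6, spurious_rate = 0,
                           edge_density = 0.013, seed = BASE_SEED)
  res <- simulate_interactome(cfg, simulate_pathways(cfg))
  n_true <- nrow(res$true_edges)
  expect_gte(n_true, 1000)
  all_keys <- unlist(lapply(res$databases, edge_key))
  votes <- table(factor(all_keys, levels = edge_key(res$true_edges)))
  se <- sqrt(5 * 0.6 * 0.4 / n_true)
  expect_lt(abs(mean(votes) - 3.0), 4 * se)
})

test_that("identical seeds reproduce byte-identical simulations", {
  cfg <- simulation_config(n_genes = 80, n_pathways = 4, n_regions = 2,
                           n_terms = 5, seed = 11)
  expect_identical(simulate_crosstalk_data(cfg), simulate_crosstalk_data(cfg))
  cfg2 <- simulation_config(n_genes = 80, n_pathways = 4, n_regions = 2,
                            n_terms = 5, seed = 12)
  expect_false(identical(edge_key(simulate_crosstalk_data(cfg)$truth$true_edges),
                         edge_key(simulate_crosstalk_data(cfg2)$truth$true_edges)))
})

test_that("pathway collections respect focal overlap construction", {
  cfg <- simulation_config(n_genes = 200, n_pathways = 8,
                           focal_overlap_range = c(1, 1), seed = 3)
  pws <- simulate_pathways(cfg)
  focal <- pws[[attr(pws, "focal")]]
  for (p in pws[setdiff(names(pws), focal$id)]) {
    expect_identical(length(intersect(p$genes, focal$genes)), 1L)
  }
  cfg1 <- simulation_config(n_pathways = 1, seed = 3)
  solo <- simulate_pathways(cfg1)
  expect_length(solo, 1L)
  expect_identical(names(solo), attr(solo, "focal"))
  # generator guarantees every non-focal pathway is a neighbor
  cfg12 <- simulation_config(n_pathways = 12, seed = 3)
  pws12 <- simulate_pathways(cfg12)
  expect_length(find_neighbor_pathways(attr(pws12, "focal"), pws12), 11L)
  expect_error(simulate_pathways(simulation_config(
    n_genes = 20, pathway_size_range = c(18, 19), n_pathways = 5, seed = 1)),
    "universe")
})

test_that("null expression yields uniform Welch p-values", {
  cfg <- simulation_config(n_genes = 600, de_effect = 0, coexpr_rho = 0,
                           n_regions = 1, seed = BASE_SEED)
  ex <- simulate_expression(cfg)[[1]]
  p <- pathwaycrosstalk:::welch_p_rows(ex$control, ex$disease)
  expect_gte(length(p), 500)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("large planted effects drive Welch p below 1e-6 in every replicate", {
  for (s in 1:3) {
    cfg <- simulation_config(n_genes = 50, n_pathways = 2,
                             pathway_size_range = c(5, 8),
                             n_control = 20, n_disease = 20,
                             de_effect = 10, coexpr_rho = 0, n_regions = 1,
                             seed = s)
    pws <- simulate_pathways(cfg)
    inter <- simulate_interactome(cfg, pws)
    tg <- plant_targets(cfg, pws, inter$true_edges)
    ex <- simulate_expression(cfg, tg)[[1]]
    p <- pathwaycrosstalk:::welch_p_rows(ex$control[tg$de_genes, , drop = FALSE],
                                         ex$disease[tg$de_genes, , drop = FALSE])
    expect_true(all(p < 1e-6))
  }
})

test_that("planted disease-only correlation is near its target", {
  cfg <- simulation_config(n_genes = 200, n_pathways = 4,
                           pathway_size_range = c(15, 25),
                           within_pathway_density = 0.5,
                           n_disease = 100, n_control = 100,
                           de_effect = 0, coexpr_rho = 0.6, n_regions = 1,
                           seed = BASE_SEED)
  pws <- simulate_pathways(cfg)
  inter <- simulate_interactome(cfg, pws)
  tg <- plant_targets(cfg, pws, inter$true_edges)
  expect_gt(nrow(tg$correlated_edges), 2)
  ex <- simulate_expression(cfg, tg)[[1]]
  r_dis <- mapply(function(a, b) cor(ex$disease[a, ], ex$disease[b, ]),
                  tg$correlated_edges$gene_a, tg$correlated_edges$gene_b)
  r_ctl <- mapply(function(a, b) cor(ex$control[a, ], ex$control[b, ]),
                  tg$correlated_edges$gene_a, tg$correlated_edges$gene_b)
  expect_lt(abs(mean(r_dis) - 0.6), 0.15)
  expect_lt(abs(mean(r_ctl)), 0.15)
})

test_that("probe replicates average back to the gene value", {
  m <- matrix(c(1, 3), nrow = 2, dimnames = list(c("g1", "g1"), "s1"))
  expect_equal(unname(collapse_probes(m)[1, 1]), 2.0)
  cfg <- simulation_config(n_genes = 30, probes_per_gene = 2, n_regions = 1,
                           n_pathways = 2, seed = 4)
  ex <- simulate_expression(cfg)[[1]]
  expect_identical(nrow(ex$control), 60L)
  expect_identical(nrow(collapse_probes(ex$control)), 30L)
})

test_that("planted annotation term can exactly cover the focal pathway", {
  cfg <- simulation_config(n_genes = 100, n_pathways = 3,
                           planted_term_enrichment = 1,
                           planted_term_background = 0, seed = 9)
  pws <- simulate_pathways(cfg)
  ann <- simulate_annotations(cfg, pws)
  planted <- attr(ann, "planted_term")
  expect_setequal(ann$gene[ann$term == planted],
                  pws[[attr(pws, "focal")]]$genes)
})
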