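test_that("overlap edges and scores follow set arithmetic", {
  m1 <- mk_mapped("P1", edges_df(c("a", "b", "c"), c("b", "c", "d")))
  m2 <- mk_mapped("P2", edges_df(c("b", "c", "d"), c("c", "d", "e")))
  ov <- overlap_edges(m1, m2)
  expect_identical(edge_key(ov), c("b|c", "c|d"))
  expect_identical(nrow(overlap_edges(m1, mk_mapped("P3", edges_df("x", "y")))), 0L)
  expect_identical(edge_key(overlap_edges(m1, m1)), edge_key(m1$edges))
  frame <- union_edge_frame(list(m1, m2))
  sc <- mk_scores(frame, c(2.0, 3.5, 1.0, 4.0))
  expect_equal(overlap_score(ov, sc[match(edge_key(ov), edge_key(sc)), ]),
               sum(sc$fisher_stat[edge_key(sc) %in% c("b|c", "c|d")]))
  expect_equal(overlap_score(ov[0, ], sc), 0)
  expect_error(overlap_score(edges_df("q", "z"), sc), "unscored")
  # symmetry on random instances
  set.seed(1)
  for (i in 1:5) {
    g <- sprintf("g%02d", 1:12)
    ma <- mk_mapped("A", edges_df(sample(g, 8, TRUE), sample(g, 8, TRUE)))
    mb <- mk_mapped("B", edges_df(sample(g, 8, TRUE), sample(g, 8, TRUE)))
    if (ma$empty || mb$empty) next
    fr <- union_edge_frame(list(ma, mb))
    s <- mk_scores(fr, runif(nrow(fr), 0, 10))
    expect_equal(overlap_score(overlap_edges(ma, mb), s),
                 overlap_score(overlap_edges(mb, ma), s))
  }
})

test_that("interaction significance is reproducible and seed-stable", {
  set.seed(2)
  g <- sprintf("g%02d", 1:20)
  frame <- canonical_edges(edges_df(sample(g, 40, TRUE), sample(g, 40, TRUE)))
  class(frame) <- c("edge_frame", "data.frame")
  sc <- mk_scores(frame, rexp(nrow(frame), 0.2))
  mi <- mk_mapped("A", frame[1:8, ])
  mj <- mk_mapped("B", frame[5:14, ])
  r1 <- interaction_significance(mi, mj, frame, sc, n_perm = 2000, seed = 42)
  r2 <- interaction_significance(mi, mj, frame, sc, n_perm = 2000, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- interaction_significance(mi, mj, frame, sc, n_perm = 10000, seed = 43)
  r4 <- interaction_significance(mi, mj, frame, sc, n_perm = 10000, seed = 44)
  pbar <- mean(c(r3$p_value, r4$p_value))
  expect_lt(abs(r3$p_value - r4$p_value),
            4 * sqrt(max(pbar * (1 - pbar), 1e-4) / 10000) * sqrt(2))
  expect_error(interaction_significance(mi, mj, frame, sc, n_perm = 0), "n_perm")
})

test_that("degenerate frame gives p = 0 under strict exceedance", {
  frame <- canonical_edges(edges_df(c("a", "b", "c"), c("b", "c", "d")))
  class(frame) <- c("edge_frame", "data.frame")
  sc <- mk_scores(frame, c(1, 2, 3))
  mp <- mk_mapped("P", frame)
  res <- interaction_significance(mp, mp, frame, sc, n_perm = 200, seed = 1)
  expect_identical(res$p_value, 0)       # every draw reproduces the frame
  res2 <- interaction_significance(mp, mp, frame, sc, n_perm = 200, seed = 1,
                                   strict = FALSE)
  expect_identical(res2$p_value, 1)      # with >= every draw ties
  smooth <- interaction_significance(mp, mp, frame, sc, n_perm = 200, seed = 1,
                                     smoothed = TRUE)
  expect_equal(smooth$p_value, 1 / 201)
})

test_that("crosstalk p-value matches an independently coded resampler", {
  set.seed(BASE_SEED)
  g <- sprintf("g%02d", 1:18)
  frame <- canonical_edges(edges_df(sample(g, 60, TRUE), sample(g, 60, TRUE)))
  frame <- frame[seq_len(min(nrow(frame), 50)), ]
  class(frame) <- c("edge_frame", "data.frame")
  sc <- mk_scores(frame, rexp(nrow(frame), 0.1))
  smap <- setNames(sc$fisher_stat, edge_key(sc))
  keys <- edge_key(frame)
  mi <- mk_mapped("A", frame[1:10, ])
  mj <- mk_mapped("B", frame[6:20, ])
  B <- 10000
  res <- interaction_significance(mi, mj, frame, sc, n_perm = B, seed = 51)
  set.seed(52)
  p_naive <- naive_interaction_p(edge_key(mi$edges), edge_key(mj$edges),
                                 keys, smap, B)
  pbar <- max(mean(c(res$p_value, p_naive)), 1e-4)
  expect_lt(abs(res$p_value - p_naive), 4 * sqrt(pbar * (1 - pbar) / B))
})

test_that("raising an overlap edge score never raises the p-value", {
  set.seed(6)
  g <- sprintf("g%02d", 1:16)
  frame <- canonical_edges(edges_df(sample(g, 50, TRUE), sample(g, 50, TRUE)))
  class(frame) <- c("edge_frame", "data.frame")
  stats0 <- rexp(nrow(frame), 0.2)
  mi <- mk_mapped("A", frame[1:9, ])
  mj <- mk_mapped("B", frame[4:12, ])
  ov_keys <- edge_key(overlap_edges(mi, mj))
  expect_gt(length(ov_keys), 0)
  bump <- which(edge_key(frame) == ov_keys[1])
  p_seq <- sapply(c(0, 5, 20, 100), function(delta) {
    st <- stats0; st[bump] <- st[bump] + delta
    interaction_significance(mi, mj, frame, mk_scores(frame, st),
                             n_perm = 3000, seed = 77)$p_value
  })
  expect_true(all(diff(p_seq) <= 0))
})

test_that("null crosstalk p-values are stochastically no smaller than uniform", {
  pall <- c()
  for (rep in 1:5) {
    cfg <- simulation_config(seed = BASE_SEED + 300 + rep, de_effect = 0,
                             coexpr_rho = 0, n_regions = 1)
    pws <- simulate_pathways(cfg)
    net <- build_ensemble_network(simulate_interactome(cfg, pws)$databases, 3)
    mapped <- lapply(c(pws[attr(pws, "focal")],
                       find_neighbor_pathways(attr(pws, "focal"), pws)),
                     map_pathway, network = net)
    mapped <- mapped[!vapply(mapped, `[[`, TRUE, "empty")]
    frame <- union_edge_frame(mapped)
    ex <- simulate_expression(cfg)[[1]]
    sc <- score_edges(frame, ex$control, ex$disease)
    ct <- crosstalk_table(mapped, sc, frame, n_perm = 300, seed = rep)
    pall <- c(pall, ct$p_value)
  }
  expect_gt(length(pall), 50)
  hit <- mean(pall <= 0.05)
  expect_lte(hit, 0.05 + 4 * sqrt(0.05 * 0.95 / length(pall)))
})

test_that("distance matrices are symmetric with unit default and zero diagonal", {
  pairs <- data.frame(pathway_i = c("P1"), pathway_j = c("P2"),
                      n_overlap_edges = 3L, overlap_score = 5,
                      p_value = 0.02)
  D <- distance_matrix(pairs, c("P1", "P2", "P3"))
  expect_identical(D["P1", "P2"], 0.02)
  expect_identical(D["P2", "P1"], 0.02)
  expect_identical(D["P1", "P3"], 1)
  expect_identical(unname(diag(D)), c(0, 0, 0))
  D0 <- distance_matrix(pairs[0, ], c("A", "B"))
  expect_identical(unname(D0["A", "B"]), 1)
})

test_that("clustering recovers planted blocks and assigns every pathway", {
  ids <- sprintf("P%02d", 1:10)
  D <- matrix(0.99, 10, 10, dimnames = list(ids, ids))
  D[1:5, 1:5] <- 0.01; D[6:10, 6:10] <- 0.01
  diag(D) <- 0
  cl <- cluster_pathways(D, min_cluster_size = 3)
  expect_identical(nrow(cl), 10L)
  expect_equal(ari(cl$cluster, rep(c(1, 2), each = 5)), 1.0)
  # permuting the input order leaves the partition unchanged (up to labels)
  perm <- sample(10)
  cl2 <- cluster_pathways(D[perm, perm], min_cluster_size = 3)
  expect_equal(ari(cl$cluster[match(ids, cl$pathway)],
                   cl2$cluster[match(ids, cl2$pathway)]), 1.0)
  # featureless matrix: all labels present, either one cluster or unassigned
  ids4 <- sprintf("Q%d", 1:4)
  D1 <- matrix(1, 4, 4, dimnames = list(ids4, ids4)); diag(D1) <- 0
  cl3 <- cluster_pathways(D1, min_cluster_size = 3)
  expect_identical(sort(cl3$pathway), sort(ids4))
  expect_true(all(cl3$cluster %in% c("C1", "unassigned")))
  expect_error(cluster_pathways(matrix(c(0, 1, 2, 0), 2,
                                       dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
  expect_identical(focal_cluster_members(cl, "P01"),
                   setdiff(cl$pathway[cl$cluster == cl$cluster[cl$pathway == "P01"]],
                           "P01"))
})
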