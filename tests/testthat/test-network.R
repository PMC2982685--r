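test_that("voting filter keeps >= min_votes and drops the rest", {
  e <- edges_df("a", "b")
  dbs5 <- list(e, e, e, edges_df("c", "d"), edges_df("c", "d"))
  net <- build_ensemble_network(dbs5, min_votes = 3)
  expect_identical(edge_key(net$edges), "a|b")     # 3 of 5: retained
  expect_identical(net$edges$votes, 3L)
  expect_false("c|d" %in% edge_key(net$edges))     # 2 of 5: excluded
  # one database, min_votes 1: identity up to dedup / self-loop removal
  db <- data.frame(gene_a = c("x", "y", "x", "z"),
                   gene_b = c("y", "x", "x", "w"))
  net1 <- build_ensemble_network(list(db), min_votes = 1)
  expect_identical(edge_key(net1$edges), c("w|z", "x|y"))
  # duplicates within a database count a single vote
  dup <- rbind(e, e, e)
  expect_identical(nrow(build_ensemble_network(list(dup, e), 2)$edges), 1L)
  expect_error(build_ensemble_network(list()), "database")
})

test_that("voting filter equals brute-force per-edge counting", {
  for (s in 1:3) {
    set.seed(s)
    genes <- sprintf("g%02d", 1:25)
    dbs <- lapply(1:5, function(i) {
      n <- sample(50:300, 1)
      edges_df(sample(genes, n, TRUE), sample(genes, n, TRUE))
    })
    net <- build_ensemble_network(dbs, min_votes = 3)
    keysets <- lapply(dbs, function(d) unique(edge_key(canonical_edges(d))))
    universe <- unique(unlist(keysets))
    brute <- sort(universe[vapply(universe, function(k) {
      sum(vapply(keysets, function(ks) k %in% ks, TRUE)) >= 3
    }, TRUE)])
    expect_identical(edge_key(net$edges), brute)
  }
})

test_that("neighbor pathways share at least one focal gene", {
  coll <- list(F = pw("F", c("g1", "g2")),
               A = pw("A", c("g2", "g9")),
               B = pw("B", c("g7", "g8")))
  nb <- find_neighbor_pathways(coll$F, coll)
  expect_identical(names(nb), "A")
  expect_error(find_neighbor_pathways("nope", coll), "focal")
})

test_that("pathway mapping prunes unexpressed and isolated genes", {
  net <- net_from_edges(edges_df("a", "b"))
  mp <- map_pathway(pw("P", c("a", "b", "c")), net,
                    expressed_genes = c("a", "b", "c"))
  expect_identical(mp$genes, c("a", "b"))
  expect_identical(edge_key(mp$edges), "a|b")
  expect_identical(mp$dropped_isolated, character())  # c never entered the network
  # a network gene that loses all induced edges is listed as isolated
  net2 <- net_from_edges(edges_df(c("a", "b"), c("b", "c")))
  mp2 <- map_pathway(pw("P", c("a", "b", "c")), net2,
                     expressed_genes = c("a", "b"))
  expect_identical(mp2$genes, c("a", "b"))
  expect_identical(mp2$dropped_isolated, character())
  mp3 <- map_pathway(pw("P", c("a", "c")), net2, expressed_genes = c("a", "c"))
  expect_true(mp3$empty)          # a-c not an edge: both isolated
  expect_identical(mp3$dropped_isolated, c("a", "c"))
  # all genes absent from expression: empty, flagged, no error
  mp4 <- map_pathway(pw("P", c("a", "b")), net, expressed_genes = character())
  expect_true(mp4$empty)
  # identity: pathway covering the network with everything expressed
  mp5 <- map_pathway(pw("P", net2$nodes), net2, expressed_genes = net2$nodes)
  expect_identical(edge_key(mp5$edges), edge_key(net2$edges))
  # idempotence: re-mapping the retained genes reproduces the mapping
  mp6 <- map_pathway(pw("P", mp5$genes), net2, expressed_genes = net2$nodes)
  expect_identical(mp6$edges, mp5$edges)
})

test_that("pathway graph records shared genes and shared edges", {
  net <- net_from_edges(edges_df(c("a", "b", "c", "d"),
                                 c("b", "c", "d", "e")))
  m1 <- map_pathway(pw("P1", c("a", "b", "c", "d")), net)
  m2 <- map_pathway(pw("P2", c("b", "c", "d", "e")), net)
  m3 <- map_pathway(pw("P3", c("x", "y")), net)
  pg <- build_pathway_graph(list(m1, m2, m3))
  expect_identical(nrow(pg$edges), 1L)   # P3 maps empty: no links
  expect_identical(pg$edges$shared_genes, 3L)
  expect_identical(pg$edges$shared_edges, 2L)   # b-c and c-d in both
  # triangle of pairwise-sharing pathways
  netT <- net_from_edges(edges_df(c("a", "b", "c"), c("b", "c", "a")))
  ms <- list(map_pathway(pw("A", c("a", "b")), netT),
             map_pathway(pw("B", c("b", "c")), netT),
             map_pathway(pw("C", c("c", "a")), netT))
  expect_identical(nrow(build_pathway_graph(ms)$edges), 3L)
  # input order invariance
  pg_rev <- build_pathway_graph(list(m3, m2, m1))
  expect_identical(pg$edges, pg_rev$edges)
})

test_that("union edge frame deduplicates with inclusion-exclusion size", {
  net <- net_from_edges(edges_df(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12)))
  keys <- edge_key(net$edges)
  m1 <- mk_mapped("P1", net$edges[1:5, ])            # 5 edges
  m2 <- mk_mapped("P2", net$edges[4:10, ])           # 7 edges, sharing 2
  frame <- union_edge_frame(list(m1, m2))
  expect_identical(nrow(frame), 10L)
  expect_identical(edge_key(frame), sort(unique(keys[1:10])))
  expect_identical(edge_key(union_edge_frame(list(m1))), keys[1:5])
  expect_identical(nrow(union_edge_frame(list(m1, m1))), 5L)
  expect_error(union_edge_frame(list(mk_mapped("E", edges_df(character(), character())))),
               "empty")
})

test_that("gene-disjoint subsample never reuses a gene and is maximal", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:30)
  frame <- canonical_edges(edges_df(sample(genes, 80, TRUE),
                                    sample(genes, 80, TRUE)))
  dj <- gene_disjoint_edges(frame)
  expect_false(anyDuplicated(c(dj$gene_a, dj$gene_b)) > 0)
  used <- c(dj$gene_a, dj$gene_b)
  rest <- frame[!(edge_key(frame) %in% edge_key(dj)), ]
  expect_true(all(rest$gene_a %in% used | rest$gene_b %in% used))
})
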