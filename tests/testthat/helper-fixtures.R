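# Shared fixtures and independent oracles, all built in code.

pw <- function(id, genes) list(id = id, name = id, genes = genes)

edges_df <- function(a, b) data.frame(gene_a = a, gene_b = b,
                                      stringsAsFactors = FALSE)

# Interaction network straight from one edge list (every edge one vote).
net_from_edges <- function(df) build_ensemble_network(list(df), min_votes = 1L)

# Hand-built mapped pathway (bypasses network mapping for crosstalk tests).
mk_mapped <- function(id, df) {
  e <- canonical_edges(df)
  structure(list(id = id, name = id,
                 genes = sort(unique(c(e$gene_a, e$gene_b))),
                 edges = e, dropped_isolated = character(),
                 n_raw_genes = length(unique(c(e$gene_a, e$gene_b))),
                 empty = nrow(e) == 0L),
            class = "mapped_pathway")
}

# Score table with prescribed S(e) values for a frame.
mk_scores <- function(frame, stats) {
  data.frame(gene_a = frame$gene_a, gene_b = frame$gene_b,
             p_diff_a = NA_real_, p_diff_b = NA_real_, p_corr = NA_real_,
             fisher_stat = stats,
             combined_p = pchisq(stats, 6, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# Independent, naively coded crosstalk resampler: character keys and %in%
# instead of integer index intersection; its own RNG usage pattern.
naive_interaction_p <- function(keys_i, keys_j, frame_keys, score_map,
                                n_perm, strict = TRUE) {
  obs <- sum(score_map[intersect(keys_i, keys_j)])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    ka <- sample(frame_keys, length(keys_i))
    kb <- sample(frame_keys, length(keys_j))
    common <- ka[ka %in% kb]
    rnd <- if (length(common)) sum(score_map[common]) else 0
    ok <- if (strict) rnd > obs else rnd >= obs
    if (ok) hits <- hits + 1L
  }
  hits / n_perm
}

# Exact enumeration oracle for the dysregulation null: all size-m subsets.
enum_dysreg_p <- function(scores_vec, m, observed, strict = TRUE) {
  sums <- combn(scores_vec, m, sum)
  if (strict) mean(sums > observed) else mean(sums >= observed)
}

# Adjusted Rand index between two labelings.
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  (a - expected) / ((b + cc) / 2 - expected)
}

# Closed-form chi-square survival for even degrees of freedom 2k:
# P(X > s) = exp(-s/2) * sum_{j=0}^{k-1} (s/2)^j / j!
chisq_sf_even <- function(s, k) {
  j <- seq_len(k) - 1
  exp(-s / 2) * sum((s / 2)^j / factorial(j))
}

# Brute-force hypergeometric upper tail by enumerating all size-m draws.
enum_hypergeom <- function(n, f, m, k) {
  annotated <- seq_len(f)
  draws <- combn(n, m)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

BASE_SEED <- 20260911L
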