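# Pathway-pathway crosstalk: overlap scores on shared interactions,
# edge-set resampling significance, distance matrices and clustering.

#' Overlapping interactions of two mapped pathways
#'
#' @param mapped_i,mapped_j [map_pathway()] results on the same network.
#' @return canonical edge data.frame (possibly empty), lexicographic order.
#' @export
overlap_edges <- function(mapped_i, mapped_j) {
  keys <- intersect(edge_key(mapped_i$edges), edge_key(mapped_j$edges))
  out <- edges_from_key(sort(keys))
  rownames(out) <- NULL
  out
}

#' Crosstalk overlap score C(P_i, P_j)
#'
#' Sum of edge dysfunction scores S(e) over the overlapping interactions of
#' two pathways.
#'
#' @param overlap edge data.frame from [overlap_edges()].
#' @param scores an [score_edges()] table covering the overlap.
#' @return non-negative numeric score (0 for an empty overlap).
#' @export
overlap_score <- function(overlap, scores) {
  if (nrow(overlap) == 0L) return(0)
  s <- score_lookup(scores)[edge_key(overlap)]
  if (anyNA(s)) {
    abort_stage("crosstalk", "overlap contains unscored edges")
  }
  sum(s)
}

#' Permutation significance of pathway-pathway crosstalk
#'
#' Null model: two edge subsets of the same sizes as the two pathways'
#' induced edge sets are drawn independently, uniformly without replacement,
#' from the pooled sampling frame; their random overlap score is the sum of
#' S(e) over the intersection. The p-value is the fraction of `n_perm`
#' random overlap scores strictly exceeding the observed score (set
#' `strict = FALSE` for >=, `smoothed = TRUE` for the (b + 1)/(B + 1)
#' estimator).
#'
#' @param mapped_i,mapped_j mapped pathways.
#' @param frame sampling frame ([union_edge_frame()]).
#' @param scores edge score table covering the frame.
#' @param n_perm number of resampling iterations (>= 1).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @param strict use strict exceedance `>` (default) rather than `>=`.
#' @param smoothed add-one smoothing of the exceedance estimate.
#' @return list of class `permutation_result`: `observed`, `p_value`,
#'   `n_perm`, `n_exceed`.
#' @export
interaction_significance <- function(mapped_i, mapped_j, frame, scores,
                                     n_perm = 10000L, seed = NULL,
                                     strict = TRUE, smoothed = FALSE) {
  n_perm <- check_count(n_perm, "n_perm", 1L)
  s <- frame_scores(frame, scores)
  nf <- length(s)
  na <- nrow(mapped_i$edges)
  nb <- nrow(mapped_j$edges)
  if (na > nf || nb > nf) {
    abort_stage("crosstalk", "pathway edge set larger than sampling frame")
  }
  observed <- overlap_score(overlap_edges(mapped_i, mapped_j), scores)
  n_exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      ia <- sample.int(nf, na)
      ib <- sample.int(nf, nb)
      rnd <- sum(s[intersect(ia, ib)])
      hit <- if (strict) rnd > observed else rnd >= observed
      if (hit) count <- count + 1L
    }
    count
  })
  p <- if (smoothed) (n_exceed + 1) / (n_perm + 1) else n_exceed / n_perm
  structure(list(observed = observed, p_value = p,
                 n_perm = n_perm, n_exceed = n_exceed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4f, p = %.6f (%d/%d exceed)\n",
              x$observed, x$p_value, x$n_exceed, x$n_perm))
  invisible(x)
}

# S(e) vector aligned to frame order; errors on unscored frame edges.
frame_scores <- function(frame, scores) {
  s <- score_lookup(scores)[edge_key(frame)]
  if (anyNA(s)) abort_stage("crosstalk", "sampling frame contains unscored edges")
  unname(s)
}

#' Crosstalk table for one region
#'
#' Computes, for every unordered pathway pair with a non-empty interaction
#' overlap, the overlap score and its permutation significance. Pairs
#' without overlapping interactions are omitted (their distance defaults
#' to 1 in [distance_matrix()]).
#'
#' @param mapped list of mapped pathways.
#' @param scores region edge score table covering the frame.
#' @param frame sampling frame.
#' @param n_perm permutations per pair.
#' @param seed master seed; each pair draws a derived stream.
#' @param strict,smoothed see [interaction_significance()].
#' @return data.frame `pathway_i`, `pathway_j`, `n_overlap_edges`,
#'   `overlap_score`, `p_value`.
#' @export
crosstalk_table <- function(mapped, scores, frame, n_perm = 10000L,
                            seed = NULL, strict = TRUE, smoothed = FALSE) {
  ids <- vapply(mapped, `[[`, "", "id")
  mapped <- mapped[order(ids)]
  ids <- sort(ids)
  rows <- list()
  for (i in seq_along(mapped)[-length(mapped)]) {
    for (j in seq((i + 1), length(mapped))) {
      ov <- overlap_edges(mapped[[i]], mapped[[j]])
      if (nrow(ov) == 0L) next
      pair_seed <- if (is.null(seed)) NULL else
        derive_seed(seed, paste("pair", ids[i], ids[j]))
      res <- interaction_significance(mapped[[i]], mapped[[j]], frame, scores,
                                      n_perm = n_perm, seed = pair_seed,
                                      strict = strict, smoothed = smoothed)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_i = ids[i], pathway_j = ids[j],
        n_overlap_edges = nrow(ov), overlap_score = res$observed,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_i = character(), pathway_j = character(),
               n_overlap_edges = integer(), overlap_score = numeric(),
               p_value = numeric())
}

#' Pathway distance matrix from crosstalk significance
#'
#' Distance between two pathways is their crosstalk permutation p-value
#' (small p-value = strong interaction = close). Pairs with no overlapping
#' interaction get distance 1; the diagonal is 0.
#'
#' @param pairs crosstalk table ([crosstalk_table()]).
#' @param ids pathway ids defining the matrix order.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(pairs, ids) {
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$pathway_i[r]; j <- pairs$pathway_j[r]
    D[i, j] <- D[j, i] <- pairs$p_value[r]
  }
  D
}

#' Cluster pathways from a crosstalk distance matrix
#'
#' Average-linkage agglomerative clustering on the significance distance
#' matrix, with an adaptive tree cut: the dendrogram is cut at
#' `cut_height` times its maximum merge height, and resulting clusters
#' smaller than `min_cluster_size` are labelled `"unassigned"` (pathways
#' that cannot be clearly grouped).
#'
#' @param D symmetric distance matrix with zero diagonal (pathway ids as
#'   dimnames).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param min_cluster_size smallest reportable cluster (default 3).
#' @param cut_height cut position as a fraction of the maximum merge height
#'   (default 0.5).
#' @return data.frame `pathway`, `cluster` (labels "C1", "C2", ... or
#'   "unassigned"), with the fitted `hclust` tree as attribute `"tree"`.
#' @export
cluster_pathways <- function(D, linkage = "average", min_cluster_size = 3L,
                             cut_height = 0.5) {
  if (!isSymmetric(unname(D)) || any(diag(D) != 0)) {
    abort_stage("cluster", "distance matrix must be symmetric with zero diagonal")
  }
  ids <- rownames(D)
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  h <- cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_cluster_size]
  label <- rep("unassigned", length(ids))
  for (k in seq_along(keep)) {
    label[raw == as.integer(keep[k])] <- sprintf("C%d", k)
  }
  out <- data.frame(pathway = ids, cluster = label, stringsAsFactors = FALSE)
  out <- out[order(out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tree") <- tree
  out
}

#' Members of the cluster containing a focal pathway
#'
#' @param assignment a [cluster_pathways()] result.
#' @param focal_id focal pathway id.
#' @return character vector of pathway ids sharing the focal pathway's
#'   cluster (excluding the focal pathway); empty if the focal pathway is
#'   unassigned.
#' @export
focal_cluster_members <- function(assignment, focal_id) {
  lab <- assignment$cluster[assignment$pathway == focal_id]
  if (length(lab) != 1L) {
    abort_stage("cluster", sprintf("focal pathway '%s' not in assignment", focal_id))
  }
  if (lab == "unassigned") return(character())
  setdiff(assignment$pathway[assignment$cluster == lab], focal_id)
}
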