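# Network assembly: voting-ensemble interaction network, pathway mapping,
# pathway-of-pathways graph, and the pooled edge sampling frame.

#' Build a voting-ensemble interaction network
#'
#' Each source database casts at most one vote per interaction (duplicates
#' within a database do not add votes); an interaction is retained when it
#' appears, in either orientation, in at least `min_votes` distinct
#' databases. The default threshold of 3 out of 5 databases follows the
#' common majority-voting rule for integrating interaction evidence.
#'
#' @param databases list of edge data.frames (columns `gene_a`, `gene_b`).
#' @param min_votes minimum number of supporting databases (default 3).
#' @return object of class `interaction_network`: list with `edges`
#'   (canonical data.frame `gene_a`, `gene_b`, `votes`) and `nodes`.
#' @export
build_ensemble_network <- function(databases, min_votes = 3L) {
  if (!is.list(databases) || length(databases) == 0L) {
    abort_stage("network", "need at least one interaction database")
  }
  min_votes <- check_count(min_votes, "min_votes", 1L)
  keys_per_db <- lapply(databases, function(db) unique(edge_key(canonical_edges(db))))
  votes <- table(unlist(keys_per_db, use.names = FALSE))
  kept <- names(votes)[votes >= min_votes]
  edges <- edges_from_key(kept)
  edges$votes <- as.integer(votes[kept])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 min_votes = min_votes,
                 n_databases = length(databases)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction network: %d nodes, %d edges (>= %d of %d database votes)\n",
              length(x$nodes), nrow(x$edges), x$min_votes, x$n_databases))
  invisible(x)
}

#' Find neighbor pathways of a focal pathway
#'
#' A neighbor pathway shares at least one gene with the focal pathway.
#'
#' @param focal a pathway (`list(id, name, genes)`) or a focal pathway id
#'   present in `collection`.
#' @param collection named list of pathways.
#' @return the neighboring pathways (excluding the focal pathway itself),
#'   sorted by pathway id.
#' @export
find_neighbor_pathways <- function(focal, collection) {
  if (is.character(focal)) {
    if (!focal %in% names(collection)) {
      abort_stage("network", sprintf("focal pathway '%s' not in collection", focal))
    }
    focal <- collection[[focal]]
  }
  others <- collection[setdiff(names(collection), focal$id)]
  keep <- vapply(others, function(p) length(intersect(p$genes, focal$genes)) > 0,
                 logical(1))
  res <- others[keep]
  res[order(names(res))]
}

#' Map a pathway onto the interaction network
#'
#' Retains the pathway genes present in both the network and the expression
#' data, induces the network edges among them, and then drops genes left
#' without any induced interaction (isolated proteins). An empty result is
#' flagged rather than raised as an error.
#'
#' @param pathway `list(id, name, genes)`.
#' @param network an [build_ensemble_network()] result.
#' @param expressed_genes character vector of genes measured in the
#'   expression data (default: all network nodes).
#' @return object of class `mapped_pathway`: list with `id`, `genes`
#'   (retained, non-isolated), `edges` (canonical induced edge data.frame),
#'   `dropped_isolated`, `n_raw_genes`, and `empty` flag.
#' @export
map_pathway <- function(pathway, network, expressed_genes = network$nodes) {
  retained <- intersect(intersect(pathway$genes, network$nodes), expressed_genes)
  idx <- network$edges$gene_a %in% retained & network$edges$gene_b %in% retained
  edges <- network$edges[idx, c("gene_a", "gene_b"), drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$gene_a, edges$gene_b))
  dropped <- setdiff(retained, connected)
  structure(list(id = pathway$id,
                 name = pathway$name,
                 genes = sort(connected),
                 edges = edges,
                 dropped_isolated = sort(dropped),
                 n_raw_genes = length(unique(pathway$genes)),
                 empty = length(connected) == 0L),
            class = "mapped_pathway")
}

#' @export
print.mapped_pathway <- function(x, ...) {
  cat(sprintf("mapped pathway %s: %d/%d genes retained, %d edges, %d isolated dropped%s\n",
              x$id, length(x$genes), x$n_raw_genes, nrow(x$edges),
              length(x$dropped_isolated), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Build the pathway-of-pathways graph
#'
#' Nodes are pathways; two pathways are linked when they share at least one
#' retained gene. Each link records both the shared retained-gene count
#' (the adjacency criterion) and the shared induced-edge count (the quantity
#' the crosstalk score sums over).
#'
#' @param mapped list of [map_pathway()] results.
#' @return object of class `pathway_graph`: list with `nodes` (pathway ids)
#'   and `edges` (data.frame `pathway_i`, `pathway_j`, `shared_genes`,
#'   `shared_edges`).
#' @export
build_pathway_graph <- function(mapped) {
  if (length(mapped) < 2L) {
    abort_stage("network", "need at least two mapped pathways")
  }
  ids <- sort(vapply(mapped, `[[`, "", "id"))
  mp <- mapped[match(ids, vapply(mapped, `[[`, "", "id"))]
  rows <- list()
  for (i in seq_along(mp)[-length(mp)]) {
    for (j in seq((i + 1), length(mp))) {
      sg <- length(intersect(mp[[i]]$genes, mp[[j]]$genes))
      if (sg >= 1L) {
        se <- length(intersect(edge_key(mp[[i]]$edges), edge_key(mp[[j]]$edges)))
        rows[[length(rows) + 1L]] <-
          data.frame(pathway_i = mp[[i]]$id, pathway_j = mp[[j]]$id,
                     shared_genes = sg, shared_edges = se,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_i = character(), pathway_j = character(),
               shared_genes = integer(), shared_edges = integer())
  structure(list(nodes = ids, edges = edges), class = "pathway_graph")
}

#' Gene-disjoint edge subsample
#'
#' Greedy maximal matching over an edge table in its stored order: keeps an
#' edge only when neither endpoint has been used by an earlier kept edge.
#' Edge scores on a gene-disjoint subsample are mutually independent under
#' a global-null expression model (scores on the full frame are not, since
#' edges sharing an endpoint share that gene's differential-expression
#' p-value), which makes the subsample the valid input for i.i.d.-based
#' calibration checks such as the Kolmogorov-Smirnov uniformity test.
#'
#' @param edges canonical edge data.frame.
#' @return subset of `edges` in which no gene appears twice.
#' @export
gene_disjoint_edges <- function(edges) {
  used <- character()
  keep <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    if (!(a %in% used) && !(b %in% used)) {
      keep[r] <- TRUE
      used <- c(used, a, b)
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled edge sampling frame
#'
#' Deduplicated union of the induced edge sets of all mapped pathways, in a
#' fixed lexicographic order by canonical endpoint pair so that permutation
#' sampling over the frame is reproducible. This is the null sampling frame
#' for both the crosstalk and the dysregulation permutation tests.
#'
#' @param mapped list of [map_pathway()] results.
#' @return canonical edge data.frame of class `edge_frame`.
#' @export
union_edge_frame <- function(mapped) {
  frames <- lapply(mapped, `[[`, "edges")
  frame <- canonical_edges(do.call(rbind, frames))
  if (nrow(frame) == 0L) {
    abort_stage("network", "edge frame is empty: nothing to score")
  }
  class(frame) <- c("edge_frame", "data.frame")
  frame
}
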