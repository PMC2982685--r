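# Intra-pathway dysregulation: summed edge scores S_P, same-size edge-set
# resampling significance, and per-region ranking.

#' Pathway dysregulation score S_P
#'
#' Sum of the edge dysfunction scores S(e) over a pathway's induced
#' interactions. A pathway with no induced interactions has no defined
#' score and returns `NA` (callers flag and exclude it from ranking).
#'
#' @param mapped a [map_pathway()] result.
#' @param scores edge score table covering the pathway's edges.
#' @return numeric score, or `NA` for an empty pathway.
#' @export
pathway_score <- function(mapped, scores) {
  if (nrow(mapped$edges) == 0L) return(NA_real_)
  overlap_score(mapped$edges, scores)
}

#' Permutation significance of pathway dysregulation
#'
#' Null model: random "pathways" of the same induced-edge count as the
#' observed pathway, drawn uniformly without replacement from the pooled
#' sampling frame; each random score is the sum of S(e) over the draw. The
#' p-value is the fraction of random scores strictly exceeding S_P
#' (`strict = FALSE` for >=; `smoothed = TRUE` for (b + 1)/(B + 1)).
#'
#' @param mapped mapped pathway with >= 1 induced edge.
#' @param frame sampling frame.
#' @param scores edge score table covering the frame.
#' @param n_perm resampling iterations.
#' @param seed RNG seed (`NULL` = current RNG state).
#' @param strict,smoothed exceedance mode, as in
#'   [interaction_significance()].
#' @return list of class `permutation_result`.
#' @export
dysregulation_significance <- function(mapped, frame, scores,
                                       n_perm = 10000L, seed = NULL,
                                       strict = TRUE, smoothed = FALSE) {
  n_perm <- check_count(n_perm, "n_perm", 1L)
  s <- frame_scores(frame, scores)
  m <- nrow(mapped$edges)
  if (m < 1L) abort_stage("dysregulation", "pathway has no induced edges")
  if (m > length(s)) {
    abort_stage("dysregulation", "pathway edge count exceeds sampling frame size")
  }
  observed <- pathway_score(mapped, scores)
  n_exceed <- with_seed(seed, {
    rnd <- vapply(seq_len(n_perm),
                  function(b) sum(s[sample.int(length(s), m)]), numeric(1))
    if (strict) sum(rnd > observed) else sum(rnd >= observed)
  })
  p <- if (smoothed) (n_exceed + 1) / (n_perm + 1) else n_exceed / n_perm
  structure(list(observed = observed, p_value = p,
                 n_perm = n_perm, n_exceed = n_exceed),
            class = "permutation_result")
}

#' Dysregulation table for one region
#'
#' Scores every mapped pathway and computes its resampling significance.
#' Pathways without induced edges are flagged (`excluded = TRUE`) and carry
#' `NA` score and p-value.
#'
#' @param mapped list of mapped pathways.
#' @param scores region edge score table.
#' @param frame sampling frame.
#' @param n_perm permutations per pathway.
#' @param seed master seed; per-pathway streams are derived from it.
#' @param strict,smoothed exceedance mode.
#' @return data.frame `pathway`, `size` (raw gene count), `n_nodes`
#'   (mapped), `n_edges`, `score`, `p_value`, `excluded`, `description`.
#' @export
dysregulation_table <- function(mapped, scores, frame, n_perm = 10000L,
                                seed = NULL, strict = TRUE, smoothed = FALSE) {
  rows <- lapply(mapped, function(mp) {
    if (mp$empty || nrow(mp$edges) == 0L) {
      return(data.frame(pathway = mp$id, size = mp$n_raw_genes,
                        n_nodes = length(mp$genes), n_edges = 0L,
                        score = NA_real_, p_value = NA_real_,
                        excluded = TRUE, description = mp$name,
                        stringsAsFactors = FALSE))
    }
    pw_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("dysreg:", mp$id))
    res <- dysregulation_significance(mp, frame, scores, n_perm = n_perm,
                                      seed = pw_seed, strict = strict,
                                      smoothed = smoothed)
    data.frame(pathway = mp$id, size = mp$n_raw_genes,
               n_nodes = length(mp$genes), n_edges = nrow(mp$edges),
               score = res$observed, p_value = res$p_value, excluded = FALSE,
               description = mp$name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank pathways by dysregulation significance
#'
#' Ascending by p-value, ties broken by descending score S_P, then by
#' pathway id; flagged (edge-less) pathways are excluded. The top `top_n`
#' pathways are returned with a `rank` column.
#'
#' @param results a [dysregulation_table()].
#' @param top_n rows to keep (default 5; `Inf` for all).
#' @return ranked data.frame.
#' @export
rank_pathways <- function(results, top_n = 5L) {
  res <- results[!results$excluded & !is.na(results$p_value), , drop = FALSE]
  if (nrow(res) == 0L) abort_stage("dysregulation", "no scorable pathways to rank")
  ord <- order(res$p_value, -res$score, res$pathway)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[seq_len(min(top_n, nrow(res))), , drop = FALSE]
  rownames(res) <- NULL
  res
}
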