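# Accumulative hypergeometric term enrichment per pathway.

#' Accumulative hypergeometric upper-tail p-value
#'
#' Probability of observing at least `k` annotated proteins in a pathway of
#' `m` proteins drawn from a universe of `n` proteins of which `f` carry
#' the annotation:
#' `p = sum_{i = k}^{min(f, m)} C(f, i) C(n - f, m - i) / C(n, m)`.
#' The sum is accumulated in log space via [lchoose()] so large universes
#' do not overflow.
#'
#' @param n universe size (nodes in the network).
#' @param f proteins annotated with the term.
#' @param m proteins in the pathway.
#' @param k observed term frequency within the pathway.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper <- function(n, f, m, k) {
  if (any(c(n, f, m, k) != floor(c(n, f, m, k))) ||
      f > n || m > n || k < 0 || k > min(f, m)) {
    abort_stage("enrichment", "require integers with f <= n, m <= n, 0 <= k <= min(f, m)")
  }
  if (k == 0) return(1)
  i <- seq(k, min(f, m))
  logs <- lchoose(f, i) + lchoose(n - f, m - i) - lchoose(n, m)
  mx <- max(logs)
  min(exp(mx + log(sum(exp(logs - mx)))), 1)
}

#' Term enrichment of one pathway
#'
#' Evaluates every annotation term present in the pathway (k >= 1) with the
#' accumulative hypergeometric test against a gene universe (by default the
#' node set of the assembled network of pathways), and returns the `top_t`
#' most significant terms. A Benjamini-Hochberg adjusted column is added
#' for convenience; ranking uses the raw p-values.
#'
#' @param pathway_genes character vector of the pathway's genes.
#' @param annotations data.frame with columns `term`, `gene` (optional
#'   `term_name`).
#' @param universe character vector of universe genes.
#' @param top_t terms to report (default 3; `Inf` for all).
#' @return data.frame `term`, `term_name`, `n`, `f`, `m`, `k`, `p_value`,
#'   `p_adjust`, `rank`, ascending in `p_value` (ties by term id).
#' @export
enrich_pathway <- function(pathway_genes, annotations, universe, top_t = 3L) {
  if (!all(c("term", "gene") %in% names(annotations))) {
    abort_stage("enrichment", "annotations need columns 'term' and 'gene'")
  }
  pw <- intersect(unique(pathway_genes), universe)
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("empty annotation table for this universe; no enrichment computed")
    return(data.frame(term = character(), term_name = character(),
                      n = integer(), f = integer(), m = integer(),
                      k = integer(), p_value = numeric(),
                      p_adjust = numeric(), rank = integer()))
  }
  n <- length(universe)
  m <- length(pw)
  ann <- ann[!duplicated(paste(ann$term, ann$gene)), , drop = FALSE]
  f_all <- table(ann$term)
  hit <- ann[ann$gene %in% pw, , drop = FALSE]
  k_all <- table(hit$term)
  terms <- names(k_all)
  if (length(terms) == 0L) {
    return(data.frame(term = character(), term_name = character(),
                      n = integer(), f = integer(), m = integer(),
                      k = integer(), p_value = numeric(),
                      p_adjust = numeric(), rank = integer()))
  }
  p <- vapply(terms, function(t) {
    hypergeom_upper(n, as.integer(f_all[t]), m, as.integer(k_all[t]))
  }, numeric(1))
  name_map <- if ("term_name" %in% names(ann)) {
    stats::setNames(ann$term_name, ann$term)
  } else stats::setNames(terms, terms)
  out <- data.frame(term = terms,
                    term_name = unname(name_map[terms]),
                    n = n, f = as.integer(f_all[terms]), m = m,
                    k = as.integer(k_all[terms]),
                    p_value = unname(p),
                    p_adjust = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[seq_len(min(top_t, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
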