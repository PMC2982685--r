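# Edge dysfunction scoring: Welch differential-expression p-values on the
# two endpoint genes, Pearson disease-condition co-expression p-value on the
# pair, combined by Fisher's method into the edge score S(e) = -2 sum(ln p).

#' Welch's two-sample t-test p-value
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs are resolved deterministically: when both
#' groups have zero variance the p-value is 1 if the means agree and
#' `p_floor` otherwise. All p-values are clamped to `[p_floor, 1]` so
#' downstream logarithms stay finite.
#'
#' @param control,disease numeric vectors (>= 2 values each).
#' @param p_floor smallest reportable p-value (default 1e-300).
#' @return p-value in `[p_floor, 1]`.
#' @export
welch_p <- function(control, disease, p_floor = 1e-300) {
  if (length(control) < 2L || length(disease) < 2L) {
    abort_stage("scoring", "Welch's t-test needs >= 2 values per group")
  }
  welch_p_rows(matrix(control, nrow = 1), matrix(disease, nrow = 1), p_floor)
}

# Row-wise Welch test: one p-value per row of the two matrices.
welch_p_rows <- function(ctrl, dis, p_floor = 1e-300) {
  n1 <- ncol(ctrl); n2 <- ncol(dis)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(dis)
  v1 <- rowSums((ctrl - m1)^2) / (n1 - 1)
  v2 <- rowSums((dis - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(nrow(ctrl))
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, p_floor)
  ok <- !degen
  if (any(ok)) {
    tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  pmin(pmax(p, p_floor), 1)
}

#' Pearson correlation test p-value
#'
#' Two-sided test of zero correlation via `t = r sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` degrees of freedom. A constant series carries no detectable
#' linear association and returns 1 with a warning; perfect correlation
#' returns `p_floor`.
#'
#' @param x,y paired numeric vectors (>= 3 values).
#' @param p_floor smallest reportable p-value.
#' @return p-value in `[p_floor, 1]`.
#' @export
pearson_p <- function(x, y, p_floor = 1e-300) {
  n <- length(x)
  if (n < 3L || length(y) != n) {
    abort_stage("scoring", "correlation test needs >= 3 paired values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined, returning p = 1")
    return(1)
  }
  r <- stats::cor(x, y)
  pearson_p_from_r(r, n, p_floor)
}

pearson_p_from_r <- function(r, n, p_floor = 1e-300) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300)),
                            n - 2, lower.tail = FALSE))
  pmin(pmax(p, p_floor), 1)
}

#' Fisher's combined probability method
#'
#' Combines k independent p-values into the statistic `-2 sum(ln p_i)`,
#' referred to the upper tail of a chi-square distribution with `2k`
#' degrees of freedom. Non-positive inputs are clamped to `p_floor` with a
#' warning.
#'
#' @param pvals numeric vector of p-values.
#' @param p_floor smallest admissible p-value.
#' @return list with `statistic` and `p_value`.
#' @export
fisher_combine <- function(pvals, p_floor = 1e-300) {
  if (length(pvals) == 0L) abort_stage("scoring", "no p-values to combine")
  if (any(pvals <= 0)) {
    warning("non-positive p-values clamped to p_floor")
  }
  p <- pmin(pmax(pvals, p_floor), 1)
  stat <- -2 * sum(log(p))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
}

#' Score every frame edge for one region
#'
#' For each interaction (x, y) in the sampling frame: `p1`, `p2` are the
#' Welch differential-expression p-values of the endpoint genes (computed
#' once per gene and reused across edges); `p3` is the Pearson co-expression
#' p-value of the pair over disease samples only. The edge dysfunction score
#' is the Fisher statistic `S(e) = -2 (ln p1 + ln p2 + ln p3)`, and the
#' combined p-value is its chi-square(6 df) upper tail. Larger S(e) means a
#' more dysfunctional interaction.
#'
#' @param frame edge frame ([union_edge_frame()]).
#' @param control,disease expression matrices (genes x samples, gene ids as
#'   row names; duplicated gene rows are probe replicates and are averaged).
#' @param p_floor smallest admissible p-value.
#' @return data.frame of class `edge_score_table` with columns `gene_a`,
#'   `gene_b`, `p_diff_a`, `p_diff_b`, `p_corr`, `fisher_stat`,
#'   `combined_p`, one row per frame edge in frame order.
#' @export
score_edges <- function(frame, control, disease, p_floor = 1e-300) {
  control <- collapse_probes(control)
  disease <- collapse_probes(disease)
  genes <- sort(unique(c(frame$gene_a, frame$gene_b)))
  missing <- setdiff(genes, intersect(rownames(control), rownames(disease)))
  if (length(missing) > 0) {
    abort_stage("scoring", sprintf(
      "frame gene(s) missing from expression data: %s",
      paste(utils::head(missing, 5), collapse = ", ")))
  }
  ctrl <- control[genes, , drop = FALSE]
  dis <- disease[genes, , drop = FALSE]
  p_gene <- welch_p_rows(ctrl, dis, p_floor)
  names(p_gene) <- genes

  # vectorized Pearson over all edges on disease samples
  n <- ncol(dis)
  centred <- dis - rowMeans(dis)
  ss <- sqrt(rowSums(centred^2))
  ia <- match(frame$gene_a, genes)
  ib <- match(frame$gene_b, genes)
  denom <- ss[ia] * ss[ib]
  r <- ifelse(denom == 0, NA_real_,
              rowSums(centred[ia, , drop = FALSE] * centred[ib, , drop = FALSE]) / denom)
  p3 <- ifelse(is.na(r), 1, pearson_p_from_r(r, n, p_floor))
  if (anyNA(r)) {
    warning("constant series on some edges: correlation p set to 1")
  }
  p1 <- p_gene[frame$gene_a]
  p2 <- p_gene[frame$gene_b]
  stat <- -2 * (log(p1) + log(p2) + log(p3))
  out <- data.frame(gene_a = frame$gene_a, gene_b = frame$gene_b,
                    p_diff_a = unname(p1), p_diff_b = unname(p2),
                    p_corr = p3, fisher_stat = stat,
                    combined_p = stats::pchisq(stat, df = 6, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_score_table", "data.frame")
  out
}

#' Average duplicated probe rows to one row per gene
#'
#' Expression matrices may carry several probes per gene (duplicated row
#' names); their values are averaged per gene.
#'
#' @param mat numeric matrix with gene ids as (possibly duplicated) row
#'   names.
#' @return matrix with unique, sorted gene row names.
#' @export
collapse_probes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) {
    return(mat[order(rownames(mat)), , drop = FALSE])
  }
  g <- factor(rownames(mat))
  out <- matrix(NA_real_, nlevels(g), ncol(mat),
                dimnames = list(levels(g), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    out[, j] <- tapply(mat[, j], g, mean)
  }
  out[order(rownames(out)), , drop = FALSE]
}

# Named score lookup: edge key -> S(e).
score_lookup <- function(scores) {
  stats::setNames(scores$fisher_stat, edge_key(scores))
}
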