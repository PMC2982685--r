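# Readers and writers for the plain-text interchange formats: GMT gene
# sets, TSV edge lists / expression matrices / sample sheets / annotations,
# GraphML networks and Newick dendrograms.

#' Read a GMT gene-set file
#'
#' Tab-separated lines: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path GMT file.
#' @return named `pathway_collection` (list of `list(id, name, genes)`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort_stage("io", sprintf("empty GMT file: %s", path))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort_stage("io", sprintf("malformed GMT line %d in %s (need id, description, >= 1 gene)",
                                i, path))
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes removed", i, fields[1]))
      genes <- unique(genes)
    }
    out[[i]] <- list(id = fields[1], name = fields[2], genes = sort(genes))
  }
  names(out) <- vapply(out, `[[`, "", "id")
  class(out) <- "pathway_collection"
  out
}

#' Write a pathway collection as GMT
#'
#' @param collection pathway collection.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(p) {
    paste(c(p$id, p$name, sort(p$genes)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read interaction databases from a TSV edge list
#'
#' Columns `gene_a`, `gene_b`, `source`; the file is split by source
#' database, each yielding one canonical edge set.
#'
#' @param path TSV file.
#' @return named list of canonical edge data.frames.
#' @export
read_edge_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("gene_a", "gene_b", "source") %in% names(df))) {
    abort_stage("io", "edge list needs columns gene_a, gene_b, source")
  }
  lapply(split(df[c("gene_a", "gene_b")], df$source), canonical_edges)
}

#' Write interaction databases as one TSV edge list
#'
#' @param databases named list of edge data.frames.
#' @param path output file.
#' @export
write_edge_lists <- function(databases, path) {
  rows <- mapply(function(db, nm) {
    cbind(db[c("gene_a", "gene_b")], source = nm)
  }, databases, names(databases), SIMPLIFY = FALSE)
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-region two-condition expression data
#'
#' The matrix TSV has a first column `gene` followed by one column per
#' sample; duplicated gene rows (multiple probes for one gene) are
#' averaged. The sample sheet TSV has columns `sample`, `region`,
#' `condition` (values `control`/`disease`) and must cover every matrix
#' column.
#'
#' @param matrix_path expression matrix TSV.
#' @param sheet_path sample sheet TSV.
#' @return named list over regions of `list(control, disease)` matrices.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  mat_df <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  if (names(mat_df)[1] != "gene") {
    abort_stage("io", "expression matrix must start with a 'gene' column")
  }
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "region", "condition") %in% names(sheet))) {
    abort_stage("io", "sample sheet needs columns sample, region, condition")
  }
  bad <- setdiff(unique(sheet$condition), c("control", "disease"))
  if (length(bad)) {
    abort_stage("io", sprintf("condition must be control/disease, found: %s",
                              paste(bad, collapse = ", ")))
  }
  samples <- names(mat_df)[-1]
  unmatched <- setdiff(samples, sheet$sample)
  if (length(unmatched)) {
    abort_stage("io", sprintf("samples missing from sheet: %s",
                              paste(utils::head(unmatched, 5), collapse = ", ")))
  }
  mat <- as.matrix(mat_df[-1])
  rownames(mat) <- mat_df$gene
  mat <- collapse_probes(mat)
  sheet <- sheet[match(samples, sheet$sample), , drop = FALSE]
  regions <- unique(sheet$region)
  out <- lapply(regions, function(reg) {
    list(control = mat[, sheet$sample[sheet$region == reg &
                                        sheet$condition == "control"],
                       drop = FALSE],
         disease = mat[, sheet$sample[sheet$region == reg &
                                        sheet$condition == "disease"],
                       drop = FALSE])
  })
  names(out) <- regions
  out
}

#' Write per-region expression data as matrix + sample sheet
#'
#' @param expression named list over regions of `list(control, disease)`.
#' @param matrix_path,sheet_path output TSV paths.
#' @export
write_expression <- function(expression, matrix_path, sheet_path) {
  mats <- list(); sheet <- list()
  for (reg in names(expression)) {
    for (cond in c("control", "disease")) {
      m <- expression[[reg]][[cond]]
      mats[[length(mats) + 1L]] <- m
      sheet[[length(sheet) + 1L]] <- data.frame(sample = colnames(m),
                                                region = reg, condition = cond,
                                                stringsAsFactors = FALSE)
    }
  }
  full <- do.call(cbind, mats)
  df <- data.frame(gene = rownames(full), full, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, sheet), sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a term-to-gene annotation table
#'
#' @param path TSV with columns `term`, `gene` and optional `term_name`.
#' @return annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% names(df))) {
    abort_stage("io", "annotation table needs columns term, gene")
  }
  df
}

#' Export an interaction or pathway graph as GraphML
#'
#' @param x an `interaction_network` or `pathway_graph`.
#' @param path output file.
#' @export
export_graphml <- function(x, path) {
  g <- if (inherits(x, "interaction_network")) {
    igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                  vertices = data.frame(name = x$nodes))
  } else if (inherits(x, "pathway_graph")) {
    igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                  vertices = data.frame(name = x$nodes))
  } else {
    abort_stage("io", "cannot export this object as GraphML")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a clustering dendrogram as Newick
#'
#' @param assignment a [cluster_pathways()] result (carries the fitted tree).
#' @param path output file.
#' @export
export_newick <- function(assignment, path) {
  tree <- attr(assignment, "tree")
  if (is.null(tree)) abort_stage("io", "assignment carries no dendrogram")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# Write a result table: p-value-like columns get a fixed 6-decimal
# human-readable rendering plus a full-precision machine column.
write_result_table <- function(df, path,
                               p_cols = intersect(c("p_value", "combined_p",
                                                    "p_adjust"), names(df))) {
  out <- df
  for (pc in p_cols) {
    out[[paste0(pc, "_full")]] <- format(df[[pc]], digits = 17, trim = TRUE,
                                         scientific = TRUE)
    out[[pc]] <- sprintf("%.6f", df[[pc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all simulated pipeline inputs to a directory
#'
#' Emits the standard formats the pipeline reads (GMT pathways, TSV edge
#' lists, expression matrix + sample sheet, annotations) and a JSON
#' ground-truth sidecar for tests.
#'
#' @param sim a [simulate_crosstalk_data()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  write_edge_lists(sim$databases, file.path(dir, "interactions.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(list(
    focal_id = truth$focal_id,
    planted_term = truth$planted_term,
    de_genes = truth$de_genes,
    true_edges = edge_key(truth$true_edges),
    correlated_edges = edge_key(truth$correlated_edges)
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
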