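# Shared helpers: canonical edge representation and reproducible seed streams.

#' Canonicalize an edge table
#'
#' Orders every edge so that `gene_a <= gene_b` lexicographically, drops
#' self-loops, and removes duplicate rows. All edge containers in the package
#' store edges in this canonical orientation so that `(a, b)` and `(b, a)`
#' are the same interaction.
#'
#' @param edges data.frame with character columns `gene_a` and `gene_b`
#'   (extra columns are preserved for the first occurrence of each edge).
#' @param dedup drop duplicated edges (default `TRUE`).
#' @return data.frame with canonical `gene_a`, `gene_b`, sorted
#'   lexicographically by (gene_a, gene_b).
#' @export
canonical_edges <- function(edges, dedup = TRUE) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  extra <- edges[keep, setdiff(names(edges), c("gene_a", "gene_b")), drop = FALSE]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE)
  if (ncol(extra)) out <- cbind(out, extra)
  if (dedup) out <- out[!duplicated(edge_key(out)), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge identity key
#'
#' @param edges canonical edge data.frame.
#' @return character vector, one key per edge ("a|b").
#' @export
edge_key <- function(edges) {
  paste(edges$gene_a, edges$gene_b, sep = "|")
}

# Split "a|b" keys back into a canonical edge table.
edges_from_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Stages
#' (and per-region repetitions within a stage) draw their own sub-seed with
#' a deterministic string-salted hash, so stages can be re-run independently
#' and still reproduce the pipeline run. Values stay below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param salt character label of the consuming stage, e.g. "expression:EC".
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(salt) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(as.character(salt))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# Run `expr` under a temporarily set RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Internal assertion with a stage-aware message.
abort_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_stage("config", sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_stage("config", sprintf("'%s' must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
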