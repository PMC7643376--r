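#' Build the within-sample binary pair-indicator matrix
#'
#' For every unordered pair of candidate genes, scores each sample 1 if
#' the first gene's expression strictly exceeds the second's within that
#' sample, and 0 otherwise (ties score 0). Pairs are stored in canonical
#' orientation, `gene_a` lexicographically before `gene_b`, one row per
#' unordered pair — the reverse orientation is its deterministic
#' complement and would duplicate the feature with flipped sign. The
#' scores depend only on within-sample orderings, so they are invariant
#' to any per-sample strictly increasing transform of expression; no
#' cross-sample normalisation is ever applied.
#'
#' @param m an `expression_matrix`.
#' @param candidates character vector of at least two genes present in `m`.
#' @param block_size number of pair rows computed per chunk; bounds
#'   transient memory for large candidate sets.
#' @return an object of class `pair_matrix`: list with `pairs` (data frame
#'   `gene_a`, `gene_b`), `sample_ids`, and `scores`, an integer 0/1
#'   matrix with `choose(length(candidates), 2)` rows (named
#'   `"geneA|geneB"`) and one column per sample.
#' @export
build_pair_matrix <- function(m, candidates, block_size = 10000L) {
  missing_genes <- setdiff(candidates, rownames(m$values))
  if (length(missing_genes)) {
    stopf("candidate gene(s) absent from the matrix: %s",
          paste(missing_genes, collapse = ", "))
  }
  candidates <- sort(unique(candidates))
  n <- length(candidates)
  if (n < 2) stopf("need at least two candidate genes")
  v <- m$values[candidates, , drop = FALSE]
  idx <- utils::combn(n, 2L)
  a_idx <- idx[1L, ]
  b_idx <- idx[2L, ]
  n_pairs <- length(a_idx)
  scores <- matrix(0L, nrow = n_pairs, ncol = ncol(v))
  for (start in seq(1L, n_pairs, by = block_size)) {
    end <- min(start + block_size - 1L, n_pairs)
    blk <- start:end
    scores[blk, ] <- (v[a_idx[blk], , drop = FALSE] >
                        v[b_idx[blk], , drop = FALSE]) + 0L
  }
  pairs <- data.frame(gene_a = candidates[a_idx], gene_b = candidates[b_idx],
                      stringsAsFactors = FALSE)
  dimnames(scores) <- list(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                           colnames(v))
  structure(list(pairs = pairs, sample_ids = colnames(v), scores = scores),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Score a single oriented gene pair across samples
#'
#' The elementary indicator: 1 where `gene_a` expression strictly exceeds
#' `gene_b` within the sample, 0 on ties or reverse order. Orientation is
#' taken as given (not canonicalised).
#'
#' @param m an `expression_matrix`.
#' @param gene_a,gene_b gene identifiers present in `m`.
#' @return named integer 0/1 vector, one element per sample.
#' @export
pair_indicator <- function(m, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m$values)) stopf("gene '%s' absent from the matrix", g)
  }
  s <- (m$values[gene_a, ] > m$values[gene_b, ]) + 0L
  names(s) <- colnames(m$values)
  s
}

#' Discard near-constant pairs
#'
#' A pair whose score is identical in more than `max_identity` of the
#' samples carries almost no ordering information and is discarded. The
#' rule is strict: a pair identical in exactly `max_identity` of samples
#' (e.g. 90 of 100 at the default 0.90) is retained.
#'
#' @param p a `pair_matrix`.
#' @param max_identity maximum tolerated fraction of identical scores.
#' @return a `pair_matrix` with the retained subset of rows; idempotent.
#' @export
filter_constant_pairs <- function(p, max_identity = 0.90) {
  frac1 <- rowMeans(p$scores)
  keep <- pmax(frac1, 1 - frac1) <= max_identity
  structure(list(pairs = p$pairs[keep, , drop = FALSE],
                 sample_ids = p$sample_ids,
                 scores = p$scores[keep, , drop = FALSE]),
            class = "pair_matrix")
}

#' Export a pair-indicator matrix as TSV
#'
#' @param p a `pair_matrix`.
#' @param path output path; rows keyed `"geneA|geneB"`.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(p, path) {
  df <- data.frame(pair = rownames(p$scores), p$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a pair matrix to samples
#' @param p a `pair_matrix`.
#' @param samples character or integer index of samples to keep.
#' @return a `pair_matrix`.
#' @export
subset_pair_matrix <- function(p, samples) {
  sc <- p$scores[, samples, drop = FALSE]
  structure(list(pairs = p$pairs, sample_ids = colnames(sc), scores = sc),
            class = "pair_matrix")
}
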