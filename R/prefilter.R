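#' Exclude patients with short or missing follow-up
#'
#' Removes patients with overall survival below `min_days` (default one
#' month = 30 days) or with missing survival time or event status, the
#' standard cohort-hygiene step before prognostic modelling.
#'
#' @param c a `clinical_table`.
#' @param min_days minimum overall-survival time in days to retain.
#' @return the filtered `clinical_table`.
#' @export
exclude_short_followup <- function(c, min_days = 30) {
  keep <- !is.na(c$os_time) & !is.na(c$os_event) & c$os_time >= min_days
  out <- c[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression between tumor and normal samples
#'
#' Tests each gene of `gene_universe` for differential expression between
#' tumor and normal samples on the log2(x + 1) scale using a two-group
#' linear model with empirical-Bayes moderated t-statistics (limma): gene
#' variances are shrunk toward a common prior whose degrees of freedom and
#' scale are moment-estimated from the data. P-values are
#' Benjamini-Hochberg adjusted across the tested family, and genes passing
#' `fdr < fdr_max` and `|log2fc| > lfc_min` are returned, labelled up/down.
#'
#' @param m an `expression_matrix` containing tumor and normal samples
#'   (at least two of each).
#' @param gene_universe character vector restricting the tested family
#'   (e.g. an RNA-binding-protein gene list); `NULL` tests all genes.
#'   Genes absent from `m` are ignored.
#' @param fdr_max,lfc_min significance and effect-size thresholds.
#' @param prior_df override for the prior degrees of freedom of the
#'   variance shrinkage; `NULL` (default) moment-estimates it via limma's
#'   empirical-Bayes machinery. `prior_df = 0` disables shrinkage, making
#'   the moderated t equal to the ordinary pooled two-sample t.
#' @param return_all if `TRUE`, return every tested gene with a
#'   `significant` flag instead of only the passing genes.
#' @return data frame with columns `gene`, `log2fc` (tumor minus normal),
#'   `t_stat`, `p_value`, `fdr`, `direction` (`"up"` iff `log2fc > 0`),
#'   ordered by increasing p-value.
#' @export
differential_expression <- function(m, gene_universe = NULL, fdr_max = 0.05,
                                    lfc_min = 0.5, prior_df = NULL,
                                    return_all = FALSE) {
  if (sum(m$group == "tumor") < 2 || sum(m$group == "normal") < 2) {
    stopf("need at least 2 tumor and 2 normal samples to estimate variances")
  }
  genes <- rownames(m$values)
  if (!is.null(gene_universe)) genes <- intersect(genes, gene_universe)
  if (!length(genes)) stopf("no genes of the universe are present in the matrix")
  y <- log2(m$values[genes, , drop = FALSE] + 1)
  grp <- factor(m$group, levels = c("normal", "tumor"))
  design <- stats::model.matrix(~grp)
  fit <- limma::lmFit(y, design)
  lfc <- fit$coefficients[, 2L]
  if (is.null(prior_df)) {
    eb <- limma::eBayes(fit)
    t_stat <- eb$t[, 2L]
    p <- eb$p.value[, 2L]
  } else {
    # explicit moderated-t with a caller-fixed prior df; prior scale
    # moment-estimated as in limma. prior_df = 0 reduces to the ordinary t.
    s2 <- fit$sigma^2
    d <- fit$df.residual
    if (prior_df > 0) {
      fd <- limma::fitFDist(s2, d)
      s2_post <- (prior_df * fd$scale + d * s2) / (prior_df + d)
    } else {
      s2_post <- s2
    }
    t_stat <- lfc / (fit$stdev.unscaled[, 2L] * sqrt(s2_post))
    p <- 2 * stats::pt(-abs(t_stat), df = d + prior_df)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = genes, log2fc = unname(lfc), t_stat = unname(t_stat),
    p_value = unname(p), fdr = unname(fdr),
    direction = ifelse(lfc > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$fdr < fdr_max & abs(out$log2fc) > lfc_min
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!return_all) {
    out <- out[out$significant, setdiff(names(out), "significant"), drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Filter DE genes to well-expressed, variable candidates
#'
#' Retains genes whose mean expression exceeds `mean_min` and whose median
#' absolute deviation exceeds `mad_min` — both strict inequalities, both
#' computed on the raw expression scale. The MAD is unscaled (median of
#' absolute deviations from the gene's median, no 1.4826 consistency
#' factor), the convention under which the default threshold 0.5 is
#' meaningful; set `mad_constant` to change it. Statistics are computed on
#' tumor samples by default since the candidates feed a tumor-only model.
#'
#' @param m an `expression_matrix`.
#' @param de_genes character vector of genes to filter (must be present in
#'   `m`).
#' @param mean_min,mad_min strict lower thresholds.
#' @param samples `"tumor"` (default) or `"all"`: which samples the
#'   statistics are computed over.
#' @param mad_constant scale factor for [stats::mad()]; default 1
#'   (unscaled).
#' @return character vector of retained genes, lexicographically sorted
#'   (a deterministic subset of `de_genes`).
#' @export
candidate_filter <- function(m, de_genes, mean_min = 0, mad_min = 0.5,
                             samples = c("tumor", "all"), mad_constant = 1) {
  samples <- match.arg(samples)
  missing_genes <- setdiff(de_genes, rownames(m$values))
  if (length(missing_genes)) {
    stopf("de_genes absent from the matrix: %s",
          paste(missing_genes, collapse = ", "))
  }
  cols <- if (samples == "tumor") m$group == "tumor" else rep(TRUE, ncol(m$values))
  v <- m$values[de_genes, cols, drop = FALSE]
  means <- rowMeans(v)
  mads <- apply(v, 1L, stats::mad, constant = mad_constant)
  sort(de_genes[means > mean_min & mads > mad_min])
}
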