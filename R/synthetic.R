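#' Generate a synthetic tumor/normal cohort with planted pair-order signal
#'
#' Emulates the statistical structure the pair-signature pipeline assumes:
#' log-normal gene expression with gene-specific means and spreads, a
#' planted fraction of differentially expressed genes shifted on the log2
#' scale in tumor samples, and a planted set of gene pairs whose
#' within-sample ordering drives survival through an exponential
#' proportional-hazards model. For each tumor sample the linear predictor
#' is `z = sum_k gamma * s_k` over the planted pairs, where `s_k = 1` iff
#' the pair's first gene exceeds its second in that sample; the death time
#' is Exponential with rate `lambda0 * exp(z)` and censoring is
#' Uniform(0, censor_max), independent of survival. Planted pair members
#' share a log-mean so their indicators are maximally informative
#' (Bernoulli(1/2)) and survive the identity filter. Age, gender and stage
#' are drawn independently of survival unless `stage_beta` is nonzero, in
#' which case `stage_beta * (stage - 1)` is added to the linear predictor.
#'
#' Because the planted predictor is a sum of `n_signal_pairs` indicators,
#' the default baseline hazard is calibrated to the median predictor:
#' `lambda0 = 5e-4 * exp(-gamma * n_signal_pairs / 2)` per day, so the
#' median-risk patient has median overall survival near 1400 days for any
#' effect size. Pass `lambda0` explicitly to override.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_genes number of genes (must be at least `2 * n_signal_pairs`).
#' @param n_signal_pairs number of planted prognostic pairs.
#' @param gamma log-hazard increment per pair indicator.
#' @param frac_de fraction of genes differentially expressed tumor vs
#'   normal (drawn outside the planted pairs).
#' @param log2fc absolute log2 fold change of the planted DE genes (random
#'   sign per gene).
#' @param signal_de if `TRUE` (default), both members of every planted
#'   pair receive a shared tumor-vs-normal shift of the same `log2fc`
#'   magnitude (random sign per pair), mirroring a pipeline in which
#'   prognostic pairs are drawn from differentially expressed genes; the
#'   shared shift leaves the within-pair ordering balanced.
#' @param lambda0 baseline hazard per day, or `NULL` for the calibrated
#'   default above.
#' @param censor_max upper bound (days) of the uniform censoring time.
#' @param stage_beta optional log-hazard per stage step (default 0: stage
#'   independent of survival).
#' @param quantize_digits optional number of decimals to round expression
#'   to, to create exact ties for exercising the tie rule; `NULL` disables.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param truth optional `synthetic_truth` from a previous call: reuses its
#'   gene panel (means, spreads, DE assignment, planted pairs and hazard
#'   parameters) and draws new samples, producing an independent cohort
#'   from the same generating process, e.g. for validation.
#' @return a list with elements `expression` (`expression_matrix`),
#'   `clinical` (`clinical_table` for the tumor samples) and `truth`
#'   (`synthetic_truth`: planted pairs with `gamma`, DE genes with true
#'   log2 fold changes, `baseline_hazard`, `censor_max`, `seed`, and the
#'   gene panel needed to regenerate).
#' @export
generate_cohort <- function(n_tumor = 400, n_normal = 50, n_genes = 200,
                            n_signal_pairs = 10, gamma = 0.8, frac_de = 0.1,
                            log2fc = 1, lambda0 = NULL, censor_max = 3650,
                            signal_de = TRUE, stage_beta = 0,
                            quantize_digits = NULL, seed, truth = NULL) {
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "synthetic_truth"))
    panel <- truth$panel
    n_genes <- length(panel$gene_means)
    n_signal_pairs <- nrow(truth$signal_pairs)
    gamma <- truth$gamma
    lambda0 <- truth$baseline_hazard
    censor_max <- truth$censor_max
    stage_beta <- truth$stage_beta
  }
  if (n_tumor < 1 || n_normal < 0 || n_genes < 2) {
    stopf("sample and gene counts must be positive")
  }
  if (n_genes < 2 * n_signal_pairs) {
    stopf("n_genes (%d) must be >= 2 * n_signal_pairs (%d)", n_genes,
          2 * n_signal_pairs)
  }
  if (frac_de < 0 || frac_de > 1) stopf("frac_de must be in [0, 1]")
  if (!is.null(lambda0) && lambda0 <= 0) stopf("lambda0 must be > 0")
  if (censor_max <= 0) stopf("censor_max must be > 0")
  lambda0 <- lambda0 %||% (5e-4 * exp(-gamma * n_signal_pairs / 2))

  with_local_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    if (is.null(truth)) {
      mu <- stats::runif(n_genes, 0.5, 5)     # natural-log scale
      sdv <- stats::runif(n_genes, 0.3, 1.0)  # spread chosen so the MAD
                                              # filter has passers and failers
      idx <- sample.int(n_genes, 2 * n_signal_pairs)
      a_idx <- idx[seq_len(n_signal_pairs)]
      b_idx <- idx[n_signal_pairs + seq_len(n_signal_pairs)]
      mu[b_idx] <- mu[a_idx]  # shared mean: indicator ~ Bernoulli(1/2)
      n_de <- round(frac_de * n_genes)
      de_pool <- setdiff(seq_len(n_genes), idx)
      de_idx <- if (n_de > 0) sample(de_pool, min(n_de, length(de_pool))) else integer()
      de_sign <- if (length(de_idx)) sample(c(-1, 1), length(de_idx), replace = TRUE) else numeric()
      names(mu) <- names(sdv) <- genes
      signal_pairs <- data.frame(gene_a = genes[a_idx], gene_b = genes[b_idx],
                                 gamma = rep(gamma, length(a_idx)),
                                 stringsAsFactors = FALSE)
      de_genes <- data.frame(gene = genes[de_idx],
                             true_log2fc = de_sign * log2fc,
                             stringsAsFactors = FALSE)
      if (signal_de && n_signal_pairs > 0) {
        # shared shift per pair: genes become DE while the within-pair
        # ordering stays Bernoulli(1/2)
        pair_sign <- sample(c(-1, 1), n_signal_pairs, replace = TRUE)
        de_genes <- rbind(de_genes, data.frame(
          gene = c(genes[a_idx], genes[b_idx]),
          true_log2fc = rep(pair_sign * log2fc, 2),
          stringsAsFactors = FALSE
        ))
      }
    } else {
      mu <- panel$gene_means
      sdv <- panel$gene_sds
      genes <- names(mu)
      signal_pairs <- truth$signal_pairs
      de_genes <- truth$de_genes
    }

    tumor_ids <- sprintf("TUM%04d", seq_len(n_tumor))
    normal_ids <- if (n_normal > 0) sprintf("NORM%04d", seq_len(n_normal)) else character()
    n_all <- n_tumor + n_normal
    logx <- matrix(stats::rnorm(n_genes * n_all, mean = mu, sd = sdv),
                   nrow = n_genes, ncol = n_all)
    if (nrow(de_genes)) {
      shift <- de_genes$true_log2fc * log(2)
      logx[match(de_genes$gene, genes), seq_len(n_tumor)] <-
        logx[match(de_genes$gene, genes), seq_len(n_tumor)] + shift
    }
    x <- exp(logx)
    if (!is.null(quantize_digits)) x <- round(x, quantize_digits)
    dimnames(x) <- list(genes, c(tumor_ids, normal_ids))
    group <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    expr <- expression_matrix(x, group)

    a_rows <- match(signal_pairs$gene_a, genes)
    b_rows <- match(signal_pairs$gene_b, genes)
    s <- x[a_rows, seq_len(n_tumor), drop = FALSE] >
      x[b_rows, seq_len(n_tumor), drop = FALSE]
    z <- gamma * colSums(s)

    age <- pmin(pmax(round(stats::rnorm(n_tumor, 65, 10)), 30), 90)
    gender <- sample(1:2, n_tumor, replace = TRUE)
    stage <- sample(1:4, n_tumor, replace = TRUE, prob = c(0.5, 0.3, 0.13, 0.07))
    t_stage <- pmin(stage + sample(0:1, n_tumor, replace = TRUE), 4)
    n_stage <- pmax(stage - sample(1:2, n_tumor, replace = TRUE), 0)
    m_stage <- as.integer(stage == 4)
    smoking <- sample(0:1, n_tumor, replace = TRUE)
    if (stage_beta != 0) z <- z + stage_beta * (stage - 1)

    death <- stats::rexp(n_tumor, rate = lambda0 * exp(z))
    censor <- stats::runif(n_tumor, 0, censor_max)
    os_time <- pmax(ceiling(pmin(death, censor)), 1)
    os_event <- as.integer(death <= censor)

    clin <- clinical_table(data.frame(
      patient_id = tumor_ids, os_time = os_time, os_event = os_event,
      age = age, gender = gender, stage = stage, t_stage = t_stage,
      n_stage = n_stage, m_stage = m_stage, smoking = smoking,
      stringsAsFactors = FALSE
    ))

    truth_out <- structure(list(
      signal_pairs = signal_pairs, de_genes = de_genes,
      baseline_hazard = lambda0, censor_max = censor_max, gamma = gamma,
      stage_beta = stage_beta, seed = seed,
      panel = list(gene_means = mu, gene_sds = sdv)
    ), class = "synthetic_truth")

    list(expression = expr, clinical = clin, truth = truth_out)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d planted pairs (gamma %.3g), %d DE genes, lambda0 %.3g/day\n",
              nrow(x$signal_pairs), x$gamma, nrow(x$de_genes), x$baseline_hazard))
  invisible(x)
}

#' Apply an independent strictly increasing transform to each sample
#'
#' Distorts expression values with a per-sample transform drawn at random
#' among affine with positive slope, power with positive exponent, and
#' scaled log1p. Every transform is strictly increasing on non-negative
#' values, so within-sample gene orderings — and therefore every pair
#' indicator and risk score — are exactly preserved. Used to demonstrate
#' and test the normalisation-free property of pair scoring.
#'
#' @param m an `expression_matrix`.
#' @param seed integer seed for the per-sample transform draws.
#' @return an `expression_matrix` of the same shape and groups.
#' @export
apply_monotone_distortion <- function(m, seed) {
  with_local_seed(seed, {
    v <- m$values
    for (j in seq_len(ncol(v))) {
      kind <- sample(c("affine", "power", "log1p"), 1L)
      v[, j] <- switch(kind,
        affine = stats::runif(1, 0.5, 3) * v[, j] + stats::runif(1, 0, 5),
        power = v[, j]^stats::runif(1, 0.5, 2),
        log1p = stats::runif(1, 0.5, 5) * log1p(v[, j])
      )
    }
    expression_matrix(v, m$group)
  })
}

#' Round expression values to create exact ties
#'
#' Quantizes an expression matrix to `digits` decimals. Used to exercise
#' the tie rule of pair scoring (tied values score 0).
#'
#' @param m an `expression_matrix`.
#' @param digits number of decimal places retained.
#' @return an `expression_matrix`.
#' @export
quantize_expression <- function(m, digits = 0) {
  expression_matrix(round(m$values, digits), m$group)
}
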