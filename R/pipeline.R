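#' Default pipeline configuration
#'
#' Every named constant of the discovery/validation pipeline with its
#' standard value: DE thresholds (`fdr_max` 0.05, `lfc_min` 0.5),
#' candidate filters (`mean_min` 0, `mad_min` 0.5), follow-up exclusion
#' (`min_days` 30), pair identity filter (`max_identity` 0.90), ROC
#' horizon (`horizon_days` 1095), cross-validation (`cv_folds` 10), the
#' covariate rosters for the Cox tables, and the covariate encodings
#' (male = 1, female = 2; stage I-IV as 1-4).
#'
#' @param ... named overrides of any config entry.
#' @return a named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    fdr_max = 0.05, lfc_min = 0.5,
    mean_min = 0, mad_min = 0.5,
    min_days = 30, max_identity = 0.90,
    horizon_days = 1095,
    cv_folds = 10, seed = 1L,
    id_prefix = NULL,
    discovery_covariates = c("age", "gender", "stage", "t_stage", "m_stage",
                             "n_stage", "risk_score"),
    validation_covariates = c("age", "gender", "smoking", "stage",
                              "risk_score"),
    encodings = list(gender = c(male = 1, female = 2),
                     stage = c(I = 1, II = 2, III = 3, IV = 4))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s': %s", name, conditionMessage(e))
  })
}

# covariates that actually vary in the cohort (degenerate ones cannot be
# modelled; e.g. a risk score that is identically zero when every
# signature gene is absent from a platform)
.usable_covariates <- function(clin, covs, scores = NULL, id_prefix = NULL) {
  df <- as.data.frame(clin)
  if (!is.null(scores)) {
    hit <- match_patient_ids(scores$sample_id, df$patient_id, prefix = id_prefix)
    df$risk_score <- NA_real_
    df$risk_score[hit[!is.na(hit)]] <- scores$score[!is.na(hit)]
  }
  covs <- intersect(covs, names(df))
  covs[vapply(covs, function(v) {
    x <- df[[v]][!is.na(df[[v]])]
    length(unique(x)) >= 2
  }, TRUE)]
}

#' Run the discovery pipeline end-to-end
#'
#' Executes the full signature-construction pipeline on a tumor/normal
#' expression cohort with clinical follow-up: short-follow-up exclusion,
#' probe/sample collapsing, differential expression of the gene universe,
#' candidate mean/MAD filtering, pair-indicator construction, identity
#' filtering, lasso Cox selection, risk scoring, 3-year time-dependent
#' ROC cutoff, stratification, Kaplan-Meier/log-rank comparison,
#' univariate and multivariate Cox regression, and subgroup survival
#' analyses. The stage funnel (genes tested, DE genes, candidates, pairs
#' built/retained, pairs selected) is recorded in `counts`.
#'
#' @param expr an `expression_matrix` with tumor and normal samples.
#' @param clin a `clinical_table` for the tumor samples.
#' @param gene_universe optional character vector restricting the DE
#'   family (e.g. the RNA-binding-protein gene list); `NULL` = all genes.
#' @param config list from [default_run_config()].
#' @param out_dir optional directory; when given, the signature, scores,
#'   groups, statistics tables and a run manifest are written there.
#' @return a results bundle (list): `signature` (with cutoff set),
#'   `scores`, `groups`, `roc`, `km`, `cox_univariate`,
#'   `cox_multivariate`, `subgroups`, `counts`, `config`.
#' @export
run_discovery <- function(expr, clin, gene_universe = NULL,
                          config = default_run_config(), out_dir = NULL) {
  counts <- list()
  clin2 <- .stage("exclude_short_followup",
                  exclude_short_followup(clin, config$min_days))
  counts$patients_retained <- nrow(clin2)
  expr2 <- .stage("collapse_duplicates", collapse_duplicates(expr))
  counts$genes <- nrow(expr2$values)
  de <- .stage("differential_expression",
               differential_expression(expr2, gene_universe,
                                       fdr_max = config$fdr_max,
                                       lfc_min = config$lfc_min))
  counts$de_genes <- nrow(de)
  # restrict to tumor samples with retained clinical follow-up
  tumor_ids <- names(expr2$group)[expr2$group == "tumor"]
  hit <- match_patient_ids(tumor_ids, clin2$patient_id, prefix = config$id_prefix)
  tumor_ids <- tumor_ids[!is.na(hit)]
  tumor <- .stage("align_samples", subset_expression(expr2, samples = tumor_ids))
  candidates <- .stage("candidate_filter",
                       candidate_filter(tumor, de$gene,
                                        mean_min = config$mean_min,
                                        mad_min = config$mad_min))
  counts$candidates <- length(candidates)
  pm <- .stage("build_pair_matrix", build_pair_matrix(tumor, candidates))
  counts$pairs_built <- nrow(pm$scores)
  pm <- .stage("filter_constant_pairs",
               filter_constant_pairs(pm, config$max_identity))
  counts$pairs_retained <- nrow(pm$scores)
  sig <- .stage("fit_lasso_cox",
                fit_lasso_cox(pm, clin2, cv_folds = config$cv_folds,
                              seed = config$seed, id_prefix = config$id_prefix))
  counts$pairs_selected <- nrow(sig$pairs)
  if (nrow(sig$pairs) == 0) {
    bundle <- list(signature = sig, scores = NULL, groups = NULL, roc = NULL,
                   km = NULL, cox_univariate = NULL, cox_multivariate = NULL,
                   subgroups = NULL, counts = counts, config = config)
    if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
    return(bundle)
  }
  scores <- .stage("score_samples", score_samples(sig, tumor))
  roc <- .stage("timedep_roc",
                timedep_roc(scores, clin2, horizon = config$horizon_days,
                            id_prefix = config$id_prefix))
  cutoff <- .stage("choose_cutoff", choose_cutoff(roc))
  sig$cutoff <- cutoff
  groups <- .stage("stratify", stratify(scores, cutoff))
  km <- .stage("km_logrank",
               km_logrank(groups, clin2, id_prefix = config$id_prefix))
  covs <- .usable_covariates(clin2, config$discovery_covariates, scores,
                             config$id_prefix)
  cox_uni <- .stage("cox_regression",
                    cox_regression(clin2, covs, scores = scores,
                                   mode = "univariate",
                                   id_prefix = config$id_prefix))
  cox_multi <- .stage("cox_regression",
                      cox_regression(clin2, covs, scores = scores,
                                     mode = "multivariate",
                                     id_prefix = config$id_prefix))
  subgroups <- .stage("subgroup_analyses", {
    res <- list()
    for (by in c("random_halves", "age_median", "gender", "stage")) {
      subsets <- subgroup_split(clin2, by, seed = config$seed)
      res[[by]] <- lapply(subsets, function(sub) {
        g <- groups[names(groups) %in% sub$patient_id]
        if (length(unique(g)) < 2 || sum(sub$os_event) < 1) return(NULL)
        km_logrank(g, sub, id_prefix = config$id_prefix)
      })
    }
    res
  })
  bundle <- list(signature = sig, scores = scores, groups = groups, roc = roc,
                 km = km, cox_univariate = cox_uni,
                 cox_multivariate = cox_multi, subgroups = subgroups,
                 counts = counts, config = config)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

#' Validate a fixed signature on an independent cohort
#'
#' Applies a signature with its learned cutoff unchanged — no refitting
#' of coefficients, no re-selection of the cutoff — to an external
#' cohort: risk scoring, stratification, Kaplan-Meier/log-rank
#' comparison, and the validation Cox models. Signature pairs whose genes
#' are absent from the cohort contribute zero and are reported per sample
#' (`scores$n_missing_pairs`).
#'
#' @param expr an `expression_matrix` (tumor samples).
#' @param clin a `clinical_table`.
#' @param sig a `pair_signature` with a non-missing cutoff.
#' @param config list from [default_run_config()].
#' @param out_dir optional output directory, as in [run_discovery()].
#' @return a results bundle (list): `scores`, `groups`, `km`,
#'   `cox_univariate`, `cox_multivariate`, `config`.
#' @export
run_validation <- function(expr, clin, sig, config = default_run_config(),
                           out_dir = NULL) {
  if (is.na(sig$cutoff)) stopf("signature cutoff is not set")
  clin2 <- .stage("exclude_short_followup",
                  exclude_short_followup(clin, config$min_days))
  expr2 <- .stage("collapse_duplicates", collapse_duplicates(expr))
  scores <- .stage("score_samples", score_samples(sig, expr2))
  groups <- .stage("stratify", stratify(scores, sig$cutoff))
  km <- if (length(unique(groups)) == 2) {
    .stage("km_logrank", km_logrank(groups, clin2, id_prefix = config$id_prefix))
  }
  covs <- .usable_covariates(clin2, config$validation_covariates, scores,
                             config$id_prefix)
  cox_uni <- if (length(covs)) {
    .stage("cox_regression",
           cox_regression(clin2, covs, scores = scores, mode = "univariate",
                          id_prefix = config$id_prefix))
  }
  cox_multi <- if (length(covs)) {
    .stage("cox_regression",
           cox_regression(clin2, covs, scores = scores, mode = "multivariate",
                          id_prefix = config$id_prefix))
  }
  bundle <- list(signature = sig, scores = scores, groups = groups, km = km,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi,
                 config = config)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$signature)) {
    write_signature(bundle$signature, file.path(out_dir, "signature.tsv"))
  }
  if (!is.null(bundle$scores)) {
    df <- as.data.frame(bundle$scores)
    df$group <- unname(bundle$groups[df$sample_id])
    utils::write.table(df, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in c("cox_univariate", "cox_multivariate")) {
    if (!is.null(bundle[[nm]])) {
      utils::write.table(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("pairsig")),
    r_version = as.character(getRversion()),
    config = bundle$config[setdiff(names(bundle$config), "encodings")],
    counts = bundle$counts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
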