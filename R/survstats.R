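#' Kaplan-Meier curves, log-rank test and group hazard ratio
#'
#' Compares survival between the high- and low-risk groups: product-limit
#' Kaplan-Meier estimate per group, two-group log-rank chi-square test,
#' and the hazard ratio (high vs low) with Wald 95% CI from a
#' single-covariate Cox fit on the group indicator (Efron tie handling).
#'
#' @param groups named character vector of `"high"`/`"low"` per sample
#'   (e.g. from [stratify()]).
#' @param c a `clinical_table` covering the samples.
#' @param id_prefix passed to [match_patient_ids()].
#' @return a list of class `km_logrank`: `fit` (a [survival::survfit]
#'   object by group), `logrank_p`, `hr`, `ci_low`, `ci_high`, `n` (per
#'   group) and `data` (the matched analysis frame).
#' @export
km_logrank <- function(groups, c, id_prefix = NULL) {
  hit <- match_patient_ids(names(groups), c$patient_id, prefix = id_prefix)
  keep <- !is.na(hit)
  g <- factor(unname(groups[keep]), levels = c("low", "high"))
  cl <- c[hit[keep], ]
  if (nlevels(droplevels(g)) < 2 || any(table(g) == 0)) {
    stopf("both risk groups must be nonempty")
  }
  if (sum(cl$os_event) < 1) stopf("no events observed")
  df <- data.frame(os_time = cl$os_time, os_event = cl$os_event, group = g)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(survival::Surv(os_time, os_event) ~ group, data = df)
  s <- summary(cox)
  structure(list(fit = fit, logrank_p = p,
                 logrank_chisq = unname(sd_$chisq),
                 hr = unname(s$conf.int[1, "exp(coef)"]),
                 ci_low = unname(s$conf.int[1, "lower .95"]),
                 ci_high = unname(s$conf.int[1, "upper .95"]),
                 n = table(g), data = df),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("km_logrank: n(low)=%d n(high)=%d, HR(high vs low)=%.3f (%.3f-%.3f), log-rank p=%.3g\n",
              x$n[["low"]], x$n[["high"]], x$hr, x$ci_low, x$ci_high,
              x$logrank_p))
  invisible(x)
}

#' Univariate and multivariate Cox proportional-hazards regression
#'
#' Fits the requested covariates against overall survival, using the
#' package's numeric encodings (stage 1-4, gender 1/2, age in years, risk
#' score continuous). Univariate mode fits each covariate alone;
#' multivariate fits all jointly. Complete-case analysis per model; ties
#' handled by the Efron approximation (day-resolution data commonly ties).
#'
#' @param c a `clinical_table`.
#' @param covariates character vector of column names to model; include
#'   `"risk_score"` to model the signature score supplied via `scores`.
#' @param scores optional `risk_scores`, merged by sample/patient id as
#'   column `risk_score`.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param id_prefix passed to [match_patient_ids()].
#' @return data frame with one row per covariate: `variable`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `model`.
#' @export
cox_regression <- function(c, covariates, scores = NULL,
                           mode = c("univariate", "multivariate"),
                           id_prefix = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(c)
  if (!is.null(scores)) {
    hit <- match_patient_ids(scores$sample_id, df$patient_id, prefix = id_prefix)
    df$risk_score <- NA_real_
    df$risk_score[hit[!is.na(hit)]] <- scores$score[!is.na(hit)]
  }
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols)) {
    stopf("covariate(s) not present: %s", paste(missing_cols, collapse = ", "))
  }
  one_fit <- function(vars, label) {
    sub <- df[stats::complete.cases(df[, c("os_time", "os_event", vars)]), ,
              drop = FALSE]
    for (v in vars) {
      if (length(unique(sub[[v]])) < 2) {
        stopf("covariate '%s' is constant in the complete-case data", v)
      }
    }
    fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                   paste(vars, collapse = " + ")))
    s <- summary(survival::coxph(fml, data = sub))
    data.frame(variable = rownames(s$conf.int),
               hr = unname(s$conf.int[, "exp(coef)"]),
               ci_low = unname(s$conf.int[, "lower .95"]),
               ci_high = unname(s$conf.int[, "upper .95"]),
               p_value = unname(s$coefficients[, "Pr(>|z|)"]),
               model = label, stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(covariates, function(v) one_fit(v, "univariate")))
  } else {
    one_fit(covariates, "multivariate")
  }
  rownames(out) <- NULL
  out
}

#' Split a cohort into clinically defined subgroups
#'
#' Partitions patients for subgroup survival validation: seeded random
#' halves, an age split at the cohort median (younger = age at or below
#' the median), or category splits on gender, stage or N stage. Every
#' patient with a recorded value falls in exactly one subset; patients
#' missing the split variable are dropped (an error if that leaves
#' nothing).
#'
#' @param c a `clinical_table`.
#' @param by one of `"random_halves"`, `"age_median"`, `"gender"`,
#'   `"stage"`, `"n_stage"`.
#' @param seed integer seed (required for `"random_halves"`).
#' @return named list of `clinical_table` subsets.
#' @export
subgroup_split <- function(c, by = c("random_halves", "age_median", "gender",
                                     "stage", "n_stage"), seed = NULL) {
  by <- match.arg(by)
  if (by == "random_halves") {
    if (is.null(seed)) stopf("random_halves requires a seed")
    n <- nrow(c)
    first <- with_local_seed(seed, sample.int(n, floor(n / 2)))
    out <- list(half1 = c[sort(first), , drop = FALSE],
                half2 = c[setdiff(seq_len(n), first), , drop = FALSE])
  } else if (by == "age_median") {
    if (all(is.na(c$age))) stopf("age is missing for every patient")
    med <- stats::median(c$age, na.rm = TRUE)
    keep <- !is.na(c$age)
    out <- list(younger = c[keep & c$age <= med, , drop = FALSE],
                older = c[keep & c$age > med, , drop = FALSE])
  } else {
    v <- c[[by]]
    if (all(is.na(v))) stopf("'%s' is missing for every patient", by)
    keep <- !is.na(v)
    out <- split(c[keep, , drop = FALSE], paste0(by, v[keep]))
  }
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Non-silent coding variant classes counted by default in TMB
#'
#' The MAF `Variant_Classification` values treated as non-silent coding
#' mutations by [compute_tmb()].
#' @format character vector.
#' @export
nonsilent_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                       "Nonstop_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                       "Splice_Site", "Translation_Start_Site")

#' Tumor mutational burden from somatic mutation records
#'
#' TMB is the number of counted somatic mutations per megabase of assayed
#' exome. By default only non-silent coding classes are counted
#' (`nonsilent_classes`); pass `classes = NULL` to count every record.
#' The exome footprint is not recorded in MAF files, so it is a
#' parameter; 38 Mb is the conventional whole-exome value.
#'
#' @param mut a `mutation_records` data frame from [read_maf()].
#' @param exome_mb assayed exome size in megabases (> 0).
#' @param classes variant classifications to count, or `NULL` for all.
#' @param sample_roster optional character vector of sample ids that must
#'   appear in the output; samples without records get count 0.
#' @return data frame with columns `sample_id`, `mutation_count`, `tmb`
#'   (count / exome_mb), one row per sample, sorted by id.
#' @export
compute_tmb <- function(mut, exome_mb = 38, classes = nonsilent_classes,
                        sample_roster = NULL) {
  if (exome_mb <= 0) stopf("exome_mb must be > 0")
  counted <- if (is.null(classes)) mut else
    mut[mut$variant_classification %in% classes, , drop = FALSE]
  tab <- table(counted$sample_id)
  ids <- sort(unique(c(names(tab), sample_roster)))
  count <- ifelse(ids %in% names(tab), as.integer(tab[ids]), 0L)
  data.frame(sample_id = ids, mutation_count = count,
             tmb = count / exome_mb, stringsAsFactors = FALSE)
}

#' Compare a per-sample quantity between risk groups (rank-sum test)
#'
#' Two-sample unpaired Wilcoxon rank-sum test of a continuous per-sample
#' value (TMB, immune fraction, microenvironment score, ...) between the
#' high- and low-risk groups: exact enumeration when both groups have at
#' most 10 untied observations, normal approximation with tie correction
#' otherwise.
#'
#' @param values named numeric vector per sample, or unnamed of the same
#'   length and order as `groups`.
#' @param groups named character vector of `"high"`/`"low"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   for high relative to low.
#' @return list with `statistic` (rank-sum W), `p_value`, and `n` per
#'   group.
#' @export
wilcoxon_compare <- function(values, groups, alternative = "two.sided") {
  if (!is.null(names(values)) && !is.null(names(groups))) {
    common <- intersect(names(values), names(groups))
    values <- values[common]
    groups <- groups[common]
  }
  hi <- values[groups == "high"]
  lo <- values[groups == "low"]
  if (!length(hi) || !length(lo)) stopf("both groups need at least one observation")
  exact <- length(hi) <= 10 && length(lo) <= 10 && !anyDuplicated(c(hi, lo))
  wt <- stats::wilcox.test(hi, lo, exact = exact, correct = TRUE,
                           alternative = alternative)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(high = length(hi), low = length(lo)))
}
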