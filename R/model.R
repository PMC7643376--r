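#' Fit an L1-penalized Cox model over pair indicators
#'
#' Selects prognostic gene pairs by lasso-penalized Cox
#' partial-likelihood regression along a regularization path, with the
#' penalty chosen by k-fold cross-validated partial likelihood (the
#' "minimum" rule). Fold assignment is seeded, making the fit fully
#' reproducible. The returned signature contains exactly the pairs with
#' nonzero coefficients at the selected penalty; its cutoff field is left
#' unset — choose one with [timedep_roc()] and [choose_cutoff()].
#'
#' @param p a `pair_matrix` of candidate pairs.
#' @param c a `clinical_table` covering the samples of `p` (matched by
#'   `patient_id`, optionally via [match_patient_ids()] prefix rules).
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param lambda optional fixed penalty, bypassing cross-validation.
#' @param refit if `TRUE`, replace the penalized coefficients with those
#'   of an unpenalized Cox refit on the selected pairs. Off by default:
#'   the shrunken coefficients are the model that was selected.
#' @param id_prefix passed to [match_patient_ids()].
#' @return a `pair_signature` with the selected pairs (possibly zero rows
#'   when the penalty shrinks everything away) and `cutoff = NA`.
#' @export
fit_lasso_cox <- function(p, c, cv_folds = 10, seed, lambda = NULL,
                          refit = FALSE, id_prefix = NULL) {
  hit <- match_patient_ids(p$sample_ids, c$patient_id, prefix = id_prefix)
  keep <- !is.na(hit)
  if (sum(keep) < cv_folds) stopf("fewer matched samples than cv_folds")
  x <- t(p$scores[, keep, drop = FALSE])
  storage.mode(x) <- "double"
  cl <- c[hit[keep], ]
  if (any(is.na(cl$os_time)) || any(is.na(cl$os_event))) {
    stopf("matched samples have missing survival information")
  }
  if (sum(cl$os_event) < 2) stopf("need at least 2 events to fit a Cox model")
  ranges <- apply(x, 2L, function(col) diff(range(col)))
  if (all(ranges == 0)) stopf("all pair features are constant")
  y <- survival::Surv(cl$os_time, cl$os_event)
  fit_coefs <- with_local_seed(seed, {
    if (is.null(lambda)) {
      foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid)
      as.numeric(stats::coef(cv, s = "lambda.min"))
    } else {
      fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1)
      as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
    }
  })
  sel <- which(fit_coefs != 0)
  pairs <- data.frame(gene_a = p$pairs$gene_a[sel],
                      gene_b = p$pairs$gene_b[sel],
                      coefficient = fit_coefs[sel],
                      stringsAsFactors = FALSE)
  if (refit && nrow(pairs)) {
    xx <- as.data.frame(x[, sel, drop = FALSE])
    names(xx) <- paste0("f", seq_along(sel))
    refit_fit <- survival::coxph(y ~ ., data = xx)
    pairs$coefficient <- unname(stats::coef(refit_fit))
    pairs <- pairs[is.finite(pairs$coefficient) & pairs$coefficient != 0, ,
                   drop = FALSE]
  }
  pair_signature(pairs,
                 metadata = sprintf("lasso Cox fit: %d candidate pairs, %d samples, %d events, %d-fold CV, seed %s",
                                    nrow(p$scores), nrow(x), sum(cl$os_event),
                                    cv_folds, format(seed)))
}

#' Compute per-sample risk scores for a signature
#'
#' Each signature pair contributes its coefficient to a sample's score iff
#' the pair's first gene strictly exceeds its second within that sample
#' (ties and reverse order contribute 0). Pairs with either gene absent
#' from the matrix contribute 0 and are counted per sample in
#' `n_missing_pairs`, keeping cross-platform validation usable; samples
#' with more than half the signature unevaluable are flagged with a
#' warning recorded in the result. Scores are computed directly from
#' expression — no renormalization of any kind.
#'
#' @param sig a `pair_signature`.
#' @param m an `expression_matrix`.
#' @return an object of class `risk_scores`: data frame with columns
#'   `sample_id`, `score`, `n_missing_pairs`, with attribute
#'   `"warning"` carrying any evaluability message.
#' @export
score_samples <- function(sig, m) {
  ns <- ncol(m$values)
  score <- numeric(ns)
  genes <- rownames(m$values)
  present <- sig$pairs$gene_a %in% genes & sig$pairs$gene_b %in% genes
  for (k in which(present)) {
    s <- m$values[sig$pairs$gene_a[k], ] > m$values[sig$pairs$gene_b[k], ]
    score <- score + sig$pairs$coefficient[k] * s
  }
  n_missing <- rep(sum(!present), ns)
  out <- data.frame(sample_id = colnames(m$values), score = score,
                    n_missing_pairs = n_missing, stringsAsFactors = FALSE)
  class(out) <- c("risk_scores", "data.frame")
  msg <- NULL
  if (nrow(sig$pairs) > 0 && sum(!present) > 0.5 * nrow(sig$pairs)) {
    msg <- sprintf("%d of %d signature pairs unevaluable in this dataset",
                   sum(!present), nrow(sig$pairs))
    warning(msg, call. = FALSE)
  }
  attr(out, "warning") <- msg
  out
}

# Product-limit (Kaplan-Meier) survival probability at a single time
# point, evaluated directly; used inside the ROC estimator where survfit
# would be called hundreds of times per curve. Cross-checked against
# survival::survfit in the test suite.
.km_surv_at <- function(time, event, t) {
  if (!length(time)) return(NA_real_)
  death_times <- sort(unique(time[event == 1 & time <= t]))
  surv <- 1
  for (tt in death_times) {
    d <- sum(time == tt & event == 1)
    r <- sum(time >= tt)  # risk set just before tt (ties: deaths at tt included)
    surv <- surv * (1 - d / r)
  }
  surv
}

#' Time-dependent ROC curve of a risk score at a fixed horizon
#'
#' Kaplan-Meier-based estimator of the ROC of a continuous risk score
#' against survival status at the horizon `t*`: with `S(t*)` the overall
#' KM survival and `S_hi`, `S_lo` the KM survival within the groups above
#' and at-or-below a cutoff `c`,
#' `sensitivity(c) = (1 - S_hi) * P(score > c) / (1 - S(t*))` and
#' `specificity(c) = S_lo * P(score <= c) / S(t*)`. Candidate cutoffs are
#' the midpoints between sorted unique scores plus minus/plus infinity;
#' estimates are clamped to `[0, 1]` (the KM plug-in can overshoot under
#' heavy censoring). The AUC is the trapezoidal area over
#' (1 - specificity, sensitivity). With no censoring before the horizon
#' the estimator reduces exactly to the classical binary ROC of the
#' event-before-horizon indicator.
#'
#' @param r a `risk_scores`.
#' @param c a `clinical_table` covering the scored samples.
#' @param horizon evaluation time in days (default 1095 = three years).
#' @param id_prefix passed to [match_patient_ids()].
#' @return an object of class `roc_curve`: list with `horizon`, `points`
#'   (data frame `cutoff`, `sensitivity`, `specificity`, ordered by
#'   cutoff) and `auc`.
#' @export
timedep_roc <- function(r, c, horizon = 1095, id_prefix = NULL) {
  hit <- match_patient_ids(r$sample_id, c$patient_id, prefix = id_prefix)
  keep <- !is.na(hit)
  score <- r$score[keep]
  cl <- c[hit[keep], ]
  time <- cl$os_time
  event <- cl$os_event
  if (horizon > max(time)) {
    stopf("horizon (%g) is beyond the last observed time (%g)", horizon, max(time))
  }
  if (!any(event == 1 & time <= horizon)) {
    stopf("no events observed before the horizon")
  }
  s_all <- .km_surv_at(time, event, horizon)
  u <- sort(unique(score))
  cutoffs <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- spec <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    hi <- score > cutoffs[i]
    p_hi <- mean(hi)
    s_hi <- if (any(hi)) .km_surv_at(time[hi], event[hi], horizon) else NA_real_
    s_lo <- if (any(!hi)) .km_surv_at(time[!hi], event[!hi], horizon) else NA_real_
    sens[i] <- if (p_hi > 0) (1 - s_hi) * p_hi / (1 - s_all) else 0
    spec[i] <- if (p_hi < 1) s_lo * (1 - p_hi) / s_all else 0
  }
  # zap accumulated floating-point dust from the KM products, then clamp
  sens <- pmin(pmax(round(sens, 12), 0), 1)
  spec <- pmin(pmax(round(spec, 12), 0), 1)
  o <- order(cutoffs)
  points <- data.frame(cutoff = cutoffs[o], sensitivity = sens[o],
                       specificity = spec[o])
  fpr <- 1 - points$specificity
  oo <- order(fpr, points$sensitivity)
  x <- fpr[oo]
  y <- points$sensitivity[oo]
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(list(horizon = horizon, points = points, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: horizon %g days, %d cutoffs, AUC %.4f\n",
              x$horizon, nrow(x$points), x$auc))
  invisible(x)
}

#' Choose the risk-score cutoff maximizing Youden's J
#'
#' Returns the cutoff with maximal `J = sensitivity + specificity - 1`,
#' the standard optimality criterion for a single operating point; ties
#' are broken toward the smaller cutoff.
#'
#' @param roc a `roc_curve`.
#' @return the chosen cutoff (numeric scalar).
#' @export
choose_cutoff <- function(roc) {
  pts <- roc$points
  if (!nrow(pts)) stopf("ROC curve has no points")
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))
  finite_best <- best[is.finite(pts$cutoff[best])]
  if (length(finite_best)) best <- finite_best
  min(pts$cutoff[best])
}

#' Stratify samples into high- and low-risk groups
#'
#' @param r a `risk_scores`.
#' @param cutoff risk-score threshold; a sample is `"high"` iff its score
#'   is strictly greater than the cutoff, `"low"` otherwise (scores equal
#'   to the cutoff are low).
#' @return named character vector of `"high"`/`"low"`, named by sample id.
#' @export
stratify <- function(r, cutoff) {
  if (is.na(cutoff)) stopf("cutoff is not set")
  out <- ifelse(r$score > cutoff, "high", "low")
  names(out) <- r$sample_id
  out
}
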