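# Independent oracles, implemented from first principles and kept separate
# from the package code paths they check.

# Two-group log-rank chi-square by direct observed-vs-expected tabulation
# over event times. Assumes no tied times (fixtures are built that way).
logrank_chisq_oracle <- function(time, event, g1) {
  o <- order(time)
  time <- time[o]; event <- event[o]; g1 <- g1[o]
  n <- length(time)
  at_risk <- n - seq_len(n) + 1L
  at_risk_g1 <- rev(cumsum(rev(g1)))
  d <- which(event == 1)
  obs <- g1[d]
  expct <- at_risk_g1[d] / at_risk[d]
  v <- expct * (1 - expct)
  sum_oe <- sum(obs - expct)
  sum_oe^2 / sum(v)
}

# Classical binary ROC of dead-by-horizon vs score at the same candidate
# cutoffs the package uses (midpoints plus +-Inf). Valid only when no
# censoring precedes the horizon.
binary_roc_oracle <- function(score, dead) {
  u <- sort(unique(score))
  cutoffs <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c0) {
      if (!any(dead)) return(0)
      sum(score > c0 & dead) / sum(dead)
    }, 0),
    specificity = vapply(cutoffs, function(c0) {
      if (all(dead)) return(0)
      sum(score <= c0 & !dead) / sum(!dead)
    }, 0)
  )
}

# Ordinary pooled-variance two-sample t statistic (tumor minus normal)
pooled_t_oracle <- function(x_tumor, x_normal) {
  n1 <- length(x_tumor); n2 <- length(x_normal)
  sp2 <- ((n1 - 1) * var(x_tumor) + (n2 - 1) * var(x_normal)) / (n1 + n2 - 2)
  (mean(x_tumor) - mean(x_normal)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
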