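test_that("exchangeable groups give log-rank p of 1 and hazard ratio 1", {
  cl <- make_clin(patient_id = sprintf("p%d", 1:6),
                  os_time = rep(c(100, 200, 300), 2),
                  os_event = rep(1, 6))
  g <- setNames(rep(c("low", "high"), each = 3), cl$patient_id[c(1:3, 1:3 + 3)])
  names(g) <- cl$patient_id
  res <- km_logrank(g, cl)
  expect_equal(res$logrank_p, 1, tolerance = 1e-9)
  expect_equal(res$hr, 1, tolerance = 1e-6)
})

test_that("the log-rank statistic matches exhaustive observed-vs-expected tabulation", {
  # high-risk patients die at days 1, 2, 3; low-risk at 4, 5, 6; all events
  cl <- make_clin(patient_id = sprintf("p%d", 1:6),
                  os_time = c(4, 5, 6, 1, 2, 3),
                  os_event = rep(1, 6))
  g <- setNames(c("low", "low", "low", "high", "high", "high"), cl$patient_id)
  # complete separation: the Cox HR legitimately diverges, only the
  # log-rank statistic is under test
  res <- suppressWarnings(km_logrank(g, cl))
  oracle <- logrank_chisq_oracle(cl$os_time, cl$os_event, g == "high")
  expect_equal(res$logrank_chisq, oracle, tolerance = 1e-8)
  expect_gt(res$hr, 1)

  # KM curves are nonincreasing step functions starting at 1
  s <- res$fit
  starts <- cumsum(c(1, head(s$strata, -1)))
  for (i in seq_along(s$strata)) {
    surv_i <- s$surv[seq(starts[i], length.out = s$strata[i])]
    expect_lte(surv_i[1], 1)
    expect_true(all(diff(surv_i) <= 0))
  }
})

test_that("the chi-square log-rank p agrees with a permutation p", {
  set.seed(301)
  n <- 40
  tm <- round(rexp(n, 1 / 600) * (1 + 0.4 * rep(0:1, each = 20))) + 1
  tm <- tm + seq_len(n) * 1e-3  # break ties for the oracle tabulation
  ev <- rbinom(n, 1, 0.8)
  g1 <- rep(c(TRUE, FALSE), each = 20)
  obs <- logrank_chisq_oracle(tm, ev, g1)
  perm <- replicate(10000, logrank_chisq_oracle(tm, ev, sample(g1)))
  p_perm <- mean(perm >= obs)
  p_chisq <- pchisq(obs, df = 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_chisq), 0.02)
})

test_that("Cox regression recovers a known hazard ratio and is reciprocal under relabeling", {
  set.seed(311)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, rate = 0.001 * exp(log(2) * x))
  cens <- runif(n, 0, 4000)
  cl <- make_clin(patient_id = sprintf("p%04d", 1:n),
                  os_time = pmax(ceiling(pmin(tm, cens)), 1),
                  os_event = as.integer(tm <= cens))
  cl$biomarker <- x
  res <- cox_regression(cl, "biomarker", mode = "univariate")
  expect_gt(res$hr, 1.8)
  expect_lt(res$hr, 2.2)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)

  cl$flipped <- 1 - x
  res2 <- cox_regression(cl, "flipped", mode = "univariate")
  expect_equal(res2$hr, 1 / res$hr, tolerance = 1e-9)
})

test_that("Wald p-values are calibrated for a covariate unrelated to survival", {
  set.seed(321)
  rejections <- replicate(200, {
    n <- 80
    tm <- rexp(n, 1 / 700)
    cens <- runif(n, 0, 2500)
    cl <- make_clin(patient_id = sprintf("p%03d", 1:n),
                    os_time = pmax(ceiling(pmin(tm, cens)), 1),
                    os_event = as.integer(tm <= cens))
    cl$noise <- rnorm(n)
    cox_regression(cl, "noise", mode = "univariate")$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("jointly prognostic stage and risk score both show HR above 1 in the multivariate model", {
  co <- generate_cohort(n_tumor = 300, n_normal = 2, n_genes = 12,
                        n_signal_pairs = 3, gamma = 0.8, stage_beta = 0.3,
                        seed = 331)
  truth_sig <- pair_signature(
    data.frame(gene_a = co$truth$signal_pairs$gene_a,
               gene_b = co$truth$signal_pairs$gene_b,
               coefficient = co$truth$signal_pairs$gamma))
  sc <- score_samples(truth_sig, subset_expression(co$expression,
                                                   samples = co$clinical$patient_id))
  res <- cox_regression(co$clinical, c("stage", "risk_score"), scores = sc,
                        mode = "multivariate")
  expect_true(all(res$hr > 1))

  cl <- co$clinical
  cl$flat <- 1
  expect_error(cox_regression(cl, "flat", mode = "univariate"), "flat")
})

test_that("subgroup splits partition the cohort", {
  cl <- make_clin(patient_id = sprintf("p%03d", 1:100),
                  os_time = 100 + 1:100, os_event = rep(c(0, 1), 50),
                  age = rep(c(40, 50, 60, 70), 25),
                  gender = rep(1:2, 50),
                  stage = rep(c(1, 1, 2, 4), 25))
  rh <- subgroup_split(cl, "random_halves", seed = 5)
  expect_equal(sort(c(rh$half1$patient_id, rh$half2$patient_id)),
               sort(cl$patient_id))
  expect_equal(nrow(rh$half1), 50)
  rh2 <- subgroup_split(cl, "random_halves", seed = 5)
  expect_identical(rh$half1$patient_id, rh2$half1$patient_id)

  am <- subgroup_split(cl, "age_median")
  expect_equal(sort(unique(am$younger$age)), c(40, 50))  # median 55
  expect_equal(sort(unique(am$older$age)), c(60, 70))

  st <- subgroup_split(cl, "stage")
  expect_setequal(names(st), c("stage1", "stage2", "stage4"))
  expect_equal(sum(vapply(st, nrow, 0L)), 100L)

  cl$stage <- NA
  expect_error(subgroup_split(cl, "stage"), "missing")
})

test_that("TMB is counted mutations per megabase and additive over record sets", {
  p <- write_tmp(toy_maf_lines, ".maf")
  rec <- read_maf(p)
  # default non-silent classes: the Silent record is not counted
  tmb <- compute_tmb(rec, exome_mb = 38)
  expect_equal(tmb$mutation_count[tmb$sample_id == "S1"], 2L)
  expect_equal(tmb$mutation_count[tmb$sample_id == "S2"], 1L)
  expect_equal(compute_tmb(rec, classes = NULL)$mutation_count,
               c(3L, 1L))
  # 76 counted mutations over 38 Mb -> TMB 2
  big <- rec[rep(1, 76), ]
  expect_equal(compute_tmb(big, exome_mb = 38)$tmb, 2)

  # roster completes absent samples with zero
  empty <- rec[0, ]
  z <- compute_tmb(empty, sample_roster = c("A", "B", "C"))
  expect_equal(z$tmb, c(0, 0, 0))

  # additivity over disjoint subsets
  t1 <- compute_tmb(rec[rec$sample_id == "S1", ], sample_roster = c("S1", "S2"))
  t2 <- compute_tmb(rec[rec$sample_id == "S2", ], sample_roster = c("S1", "S2"))
  expect_equal(t1$mutation_count + t2$mutation_count,
               compute_tmb(rec, sample_roster = c("S1", "S2"))$mutation_count)
})

test_that("rank-sum comparisons are exact on small groups and calibrated on null data", {
  vals <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)
  grp <- c(a = "high", b = "high", c = "high", d = "low", e = "low", f = "low")
  # the most extreme of the C(6,3) = 20 labelings
  res <- wilcoxon_compare(vals, grp, alternative = "less")
  expect_equal(res$p_value, 1 / 20)

  same <- wilcoxon_compare(c(1, 2, 3, 1, 2, 3),
                           rep(c("high", "low"), each = 3))
  expect_equal(same$p_value, 1)

  expect_error(wilcoxon_compare(vals, setNames(rep("high", 6), names(vals))),
               "both groups")

  set.seed(341)
  rej <- replicate(200, {
    v <- rnorm(60)
    g <- rep(c("high", "low"), each = 30)
    wilcoxon_compare(v, g)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
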