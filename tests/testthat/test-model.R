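test_that("full shrinkage yields an empty signature and missing events error", {
  co <- generate_cohort(n_tumor = 60, n_normal = 2, n_genes = 16,
                        n_signal_pairs = 3, seed = 201)
  pm <- build_pair_matrix(co$expression, rownames(co$expression$values))
  pm <- subset_pair_matrix(pm, co$clinical$patient_id)
  sig <- fit_lasso_cox(pm, co$clinical, seed = 1, lambda = 10)
  expect_equal(nrow(sig$pairs), 0L)

  cl <- co$clinical
  cl$os_event <- 0
  expect_error(fit_lasso_cox(pm, cl, seed = 1), "events")
})

test_that("a single dominant planted pair gets the largest positive coefficient", {
  co <- generate_cohort(n_tumor = 500, n_normal = 2, n_genes = 12,
                        n_signal_pairs = 1, gamma = 3, seed = 211)
  pm <- filter_constant_pairs(
    subset_pair_matrix(build_pair_matrix(co$expression,
                                         rownames(co$expression$values)),
                       co$clinical$patient_id))
  sig <- fit_lasso_cox(pm, co$clinical, seed = 2, lambda = 0.001)
  tp <- co$truth$signal_pairs
  key <- paste(pmin(tp$gene_a, tp$gene_b), pmax(tp$gene_a, tp$gene_b))
  got <- paste(sig$pairs$gene_a, sig$pairs$gene_b)
  expect_true(key %in% got)
  k <- which(got == key)
  # planted orientation may be flipped by canonicalization
  flipped <- tp$gene_a > tp$gene_b
  coef_k <- sig$pairs$coefficient[k] * ifelse(flipped, -1, 1)
  expect_gt(coef_k, 0)
  expect_equal(which.max(abs(sig$pairs$coefficient)), k)
})

test_that("lasso fits are reproducible from the fold seed", {
  co <- generate_cohort(n_tumor = 120, n_normal = 2, n_genes = 20,
                        n_signal_pairs = 4, seed = 221)
  pm <- filter_constant_pairs(
    subset_pair_matrix(build_pair_matrix(co$expression,
                                         rownames(co$expression$values)),
                       co$clinical$patient_id))
  s1 <- fit_lasso_cox(pm, co$clinical, seed = 7)
  s2 <- fit_lasso_cox(pm, co$clinical, seed = 7)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("risk scores are coefficient sums over satisfied pair orderings", {
  sig <- pair_signature(data.frame(gene_a = c("A", "C"),
                                   gene_b = c("B", "D"),
                                   coefficient = c(0.5, -0.3)))
  v <- mat(c(2, 1,
             1, 2,
             5, 1,
             1, 5), c("A", "B", "C", "D"), c("s1", "s2"))
  r <- score_samples(sig, make_expr(v))
  expect_equal(r$score[r$sample_id == "s1"], 0.2)  # A>B and C>D: 0.5 - 0.3
  expect_equal(r$score[r$sample_id == "s2"], 0)    # no ordering satisfied
  expect_equal(r$n_missing_pairs, c(0L, 0L))
  # bounded by the sums of negative and positive coefficients
  expect_true(all(r$score >= -0.3 & r$score <= 0.5))
})

test_that("the packaged signature scores the all-orderings-satisfied sample at the coefficient sum", {
  sig <- load_packaged_signature()
  # topologically order the pair digraph, then assign decreasing values so
  # gene_a > gene_b holds for all 33 pairs simultaneously
  remaining <- signature_genes(sig)
  e <- sig$pairs
  topo <- character()
  while (length(remaining)) {
    src <- setdiff(remaining, e$gene_b)
    expect_true(length(src) > 0)  # pair digraph is acyclic
    topo <- c(topo, src)
    remaining <- setdiff(remaining, src)
    e <- e[!(e$gene_a %in% src), , drop = FALSE]
  }
  v <- matrix(as.numeric(rev(seq_along(topo))), ncol = 1,
              dimnames = list(topo, "s1"))
  r <- score_samples(sig, make_expr(v))
  # independently computed sum of the published coefficient column
  expect_equal(r$score, 0.479067, tolerance = 1e-9)
})

test_that("pairs with absent genes contribute zero and are reported", {
  sig <- pair_signature(data.frame(gene_a = c("A", "X"), gene_b = c("B", "Y"),
                                   coefficient = c(0.5, 9)))
  v <- mat(c(2, 1), c("A", "B"), "s1")
  r <- score_samples(sig, make_expr(v))
  expect_equal(r$score, 0.5)
  expect_equal(r$n_missing_pairs, 1L)

  none <- mat(c(1, 2), c("Q", "R"), "s1")
  expect_warning(r2 <- score_samples(sig, make_expr(none)), "unevaluable")
  expect_equal(r2$score, 0)
  expect_equal(r2$n_missing_pairs, 2L)
  expect_match(attr(r2, "warning"), "2 of 2")
})

test_that("risk scores are exactly invariant to per-sample monotone transforms", {
  m <- random_expr(20, 15, seed = 231)
  g <- rownames(m$values)
  sig <- pair_signature(data.frame(gene_a = g[1:5], gene_b = g[6:10],
                                   coefficient = c(0.4, -0.2, 1.1, -0.7, 0.05)))
  ref <- score_samples(sig, m)
  for (s in 1:5) {
    d <- apply_monotone_distortion(m, seed = s)
    expect_identical(score_samples(sig, d)$score, ref$score)
  }
})

test_that("a perfectly separating score has time-dependent AUC 1", {
  n <- 40
  score <- seq_len(n)
  cl <- make_clin(patient_id = sprintf("p%02d", 1:n),
                  os_time = ifelse(score > 20, 500, 2000),
                  os_event = 1)
  r <- structure(data.frame(sample_id = cl$patient_id, score = score,
                            n_missing_pairs = 0L),
                 class = c("risk_scores", "data.frame"))
  roc <- timedep_roc(r, cl, horizon = 1095)
  expect_equal(roc$auc, 1)
  expect_true(all(roc$points$sensitivity >= 0 & roc$points$sensitivity <= 1))
  expect_true(all(roc$points$specificity >= 0 & roc$points$specificity <= 1))
  expect_false(is.unsorted(roc$points$cutoff))
  expect_error(timedep_roc(r, cl, horizon = 5000), "beyond")
})

test_that("without censoring the estimator reduces to the classical binary ROC", {
  set.seed(241)
  n <- 60
  score <- rnorm(n)
  cl <- make_clin(patient_id = sprintf("p%02d", 1:n),
                  os_time = round(rexp(n, 1 / 900)) + 1,
                  os_event = 1)
  r <- structure(data.frame(sample_id = cl$patient_id, score = score,
                            n_missing_pairs = 0L),
                 class = c("risk_scores", "data.frame"))
  roc <- timedep_roc(r, cl, horizon = 1095)
  oracle <- binary_roc_oracle(score, cl$os_time <= 1095)
  expect_equal(roc$points$sensitivity, oracle$sensitivity, tolerance = 1e-12)
  expect_equal(roc$points$specificity, oracle$specificity, tolerance = 1e-12)
  # sensitivity nonincreasing, specificity nondecreasing in the cutoff
  expect_true(all(diff(roc$points$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$points$specificity) >= -1e-12))
})

test_that("scores unrelated to survival give AUC near one half", {
  set.seed(251)
  aucs <- replicate(200, {
    n <- 40
    tm <- round(rexp(n, 1 / 800)) + 1
    cens <- round(runif(n, 1, 2000))
    cl <- make_clin(patient_id = sprintf("p%02d", 1:n),
                    os_time = pmax(pmin(tm, cens), 1),
                    os_event = as.integer(tm <= cens))
    r <- structure(data.frame(sample_id = cl$patient_id, score = rnorm(n),
                              n_missing_pairs = 0L),
                   class = c("risk_scores", "data.frame"))
    tryCatch(timedep_roc(r, cl, horizon = 1000)$auc, error = function(e) NA)
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.03)
})

test_that("Youden cutoff selection breaks ties toward the smaller cutoff", {
  pts <- data.frame(cutoff = 1:5,
                    sensitivity = c(0.9, 0.8, 0.9, 0.5, 0.2),
                    specificity = c(0.2, 0.6, 0.5, 0.7, 0.8))
  # J = 0.1, 0.4, 0.4, 0.2, 0 -> argmax at cutoffs 2 and 3, pick 2
  roc <- structure(list(horizon = 1095, points = pts, auc = NA_real_),
                   class = "roc_curve")
  expect_equal(choose_cutoff(roc), 2)

  # degenerate: all scores identical -> J = 0 everywhere
  cl <- make_clin(patient_id = c("p1", "p2", "p3"),
                  os_time = c(200, 1200, 2000), os_event = c(1, 1, 1))
  r <- structure(data.frame(sample_id = cl$patient_id, score = c(1, 1, 1),
                            n_missing_pairs = 0L),
                 class = c("risk_scores", "data.frame"))
  roc2 <- timedep_roc(r, cl, horizon = 1500)
  j <- roc2$points$sensitivity + roc2$points$specificity - 1
  expect_equal(max(j), 0)
  expect_equal(choose_cutoff(roc2), -Inf)
})

test_that("stratification is strict at the cutoff", {
  r <- structure(data.frame(sample_id = c("a", "b", "c"),
                            score = c(-0.07, -0.075, -0.08),
                            n_missing_pairs = 0L),
                 class = c("risk_scores", "data.frame"))
  g <- stratify(r, -0.075)
  expect_identical(unname(g), c("high", "low", "low"))
  expect_error(stratify(r, NA_real_), "not set")
})
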