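---
title: "Rank-based gene-pair prognostic signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair prognostic signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The problem and the model

Prognostic expression signatures built from absolute expression levels
travel poorly between platforms: FPKM from one RNA-seq pipeline and
probe intensities from a microarray are not on a common scale, and
cross-sample normalisation schemes each introduce their own artefacts.
`pairsig` implements the *relative-ordering* alternative: every feature
is a binary within-sample comparison of two genes,

$$ s_{k}(i) \;=\; \mathbf{1}\{\,x_{a_k}(i) > x_{b_k}(i)\,\}, $$

where $x_g(i)$ is the expression of gene $g$ in sample $i$. Because
$s_k$ depends only on the ordering of two measurements made inside one
sample, it is exactly invariant to any strictly increasing per-sample
transform of expression — which covers scale changes, library-size
factors, log transforms and monotone background corrections. Ties score
0 (the rule is a strict inequality); this matters only for quantized
data and is exercised explicitly in the tests via a quantization option
in the data generator.

A signature is an ordered list of pairs with Cox regression
coefficients $\beta_k$; the risk score of sample $i$ is

$$ r(i) \;=\; \sum_k \beta_k \, s_k(i), $$

and patients with $r(i)$ strictly above a fixed cutoff are called
high-risk. The package ships a published 33-pair RNA-binding-protein
(RBP) signature for lung adenocarcinoma (49 distinct genes, cutoff
$-0.075$) as `load_packaged_signature()`, usable on any gene-level
expression table without renormalisation.

## Pipeline stages and their parameters

`run_discovery()` composes the stages below; each is exported and
individually testable. Defaults live in `default_run_config()`.

**Cohort hygiene** (`exclude_short_followup`): patients with overall
survival below 30 days or missing survival information are removed.
Deaths within the first month are dominated by perioperative and
comorbid causes rather than tumor biology, and they distort both the
Cox fits and the ROC estimate.

**Collapsing** (`collapse_duplicates`): multiple probes per gene and
multiple samples per patient are collapsed by arithmetic means, probes
first. Collapsing precedes all analysis: pair indicators are only
meaningful on one value per gene per patient, so the pipeline resolves
the probe level before any scoring.

**Differential expression** (`differential_expression`): two-group
limma fit on $\log_2(x+1)$-transformed values, empirical-Bayes
moderated t, Benjamini–Hochberg adjustment across the tested family
(typically a curated RBP gene universe). Genes pass at FDR $< 0.05$
and $|\log_2 \mathrm{FC}| > 0.5$. Two choices deserve note. First, the
$\log_2(x+1)$ transform: FPKM-like values are heavily right-skewed and
the linear model needs roughly symmetric errors; the $+1$ keeps zeros
finite at the cost of compressing fold changes for genes expressed
near zero. Second, the fold-change filter is two-sided — both up- and
down-regulated genes are biologically eligible pair members. The
`prior_df` argument exposes the variance-shrinkage degrees of freedom;
`prior_df = 0` reduces the moderated t exactly to the ordinary pooled
two-sample t, which is how the test suite anchors the statistic to a
closed form.

**Candidate filtering** (`candidate_filter`): DE genes must have mean
expression $> 0$ and unscaled median absolute deviation $> 0.5$
(median of absolute deviations from the gene's median, no 1.4826
consistency factor — the threshold is only meaningful under one
convention, and this is the one under which near-constant genes fall
at 0). Both inequalities are strict, so a constant gene (MAD exactly
0) and a gene at MAD exactly 0.5 are excluded and the boundary is
testable. Statistics are computed on tumor samples by default, since
the candidates feed a tumor-only survival model; `samples = "all"` is
available.

**Pair space** (`build_pair_matrix`, `filter_constant_pairs`): one row
per unordered candidate pair in canonical lexicographic orientation
($a < b$); the reverse orientation is the deterministic complement
$1 - s$ and would enter the penalized model as the same feature with
flipped sign. Pairs whose score is identical in *more than* 90% of
samples are discarded — a pair at exactly 90% identity is retained
(strict rule). The matrix is computed in row blocks so that large
candidate sets (hundreds of genes, tens of thousands of pairs) stay
within ordinary memory.

**Model fitting** (`fit_lasso_cox`): L1-penalized Cox partial
likelihood over the binary pair features (glmnet), penalty chosen by
10-fold cross-validated partial likelihood at its optimum (the
"minimum" rule, not 1-SE). The denser minimum rule is deliberate: the
method's value lies in a sparse-but-not-minimal pair set, and the 1-SE
rule on tens of thousands of weakly correlated binary features tends
to collapse to very few pairs. Fold assignment is seeded, making fits
bit-reproducible. Coefficients are reported as fitted (shrunken); an
unpenalized refit on the selected pairs is available behind
`refit = TRUE` but off by default, since the shrunken coefficients are
the model the cross-validation actually selected.

**Cutoff selection** (`timedep_roc`, `choose_cutoff`): time-dependent
ROC of the risk score at a 1095-day (three-year) horizon, with the
Kaplan–Meier plug-in estimator: writing $S(t^*)$ for overall KM
survival at the horizon and $S_{hi}, S_{lo}$ for KM survival above and
at-or-below a cutoff $c$,

$$ \mathrm{sens}(c) = \frac{(1 - S_{hi})\,P(r > c)}{1 - S(t^*)},
\qquad
\mathrm{spec}(c) = \frac{S_{lo}\,P(r \le c)}{S(t^*)}. $$

Candidate cutoffs are the midpoints between sorted unique scores plus
$\pm\infty$; AUC is the trapezoid over $(1-\mathrm{spec},
\mathrm{sens})$. The KM plug-in can overshoot $[0,1]$ under heavy
censoring, so estimates are clamped after rounding away
floating-point dust at the 12th decimal (products of many survival
factors otherwise leave $10^{-16}$-scale residue that breaks exact
corner cases). With no censoring before the horizon the estimator
reduces point-by-point to the classical binary ROC of the
dead-by-horizon indicator — the test suite asserts this reduction
exactly. The operating cutoff maximizes Youden's $J = \mathrm{sens} +
\mathrm{spec} - 1$, ties broken toward the smaller cutoff (the more
inclusive high-risk call); "high" means strictly above the cutoff.

**Survival statistics** (`km_logrank`, `cox_regression`,
`subgroup_split`, `compute_tmb`, `wilcoxon_compare`): standard
survival-package machinery behind a stable surface — product-limit
curves, two-group log-rank, Cox fits with Efron tie handling
(day-resolution times tie frequently), complete-case covariate
handling, seeded random-halves and clinical subgroup splits. Covariate
encodings are numeric: age in years, gender male = 1 / female = 2,
stage I–IV as 1–4. Tumor mutational burden is counted mutations per
megabase over a configurable exome footprint (default 38 Mb, the
conventional whole-exome size, since MAF files do not record it); by
default only non-silent coding classes are counted. Risk-group
comparisons of continuous quantities use the unpaired Wilcoxon
rank-sum test — groups defined by a risk cutoff are independent
samples, so the paired signed-rank variant would be a misapplication —
with exact enumeration for groups of at most 10 untied values and the
tie-corrected normal approximation otherwise.

**Validation** (`run_validation`): the signature and its cutoff are
applied unchanged to external cohorts. Signature pairs with a gene
absent from the platform contribute 0 and are counted per sample; a
sample with more than half its pairs unevaluable triggers a recorded
warning rather than an error, keeping cross-platform validation usable
while making its limits visible.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture: it
produces tumor/normal cohorts in which every pipeline stage has known
ground truth (`synthetic_truth`).

* **Expression** is log-normal: gene $g$ has log-scale mean $\mu_g \sim
  U(0.5, 5)$ and spread $\sigma_g \sim U(0.3, 1)$. The spread range is
  chosen so the MAD $> 0.5$ filter has both passers and failers and is
  therefore exercised nontrivially.
* **Differential expression** shifts a fraction `frac_de` of genes by
  `log2fc` (random sign) in tumor samples. Both members of each planted
  prognostic pair also receive a *shared* shift by default
  (`signal_de = TRUE`): in the emulated study design prognostic pairs
  are drawn from DE genes, and a shared shift makes the pair members DE
  without biasing their within-pair ordering.
* **Planted pairs** share a log-mean, so each indicator is
  Bernoulli(1/2) and survives the 90% identity filter by construction.
* **Survival** follows an exponential proportional-hazards model — the
  simplest model consistent with the Cox analyses downstream. The
  linear predictor of a tumor sample is $z = \gamma \sum_k s_k$ over
  the planted pairs; death time is $\mathrm{Exp}(\lambda_0 e^{z})$,
  censoring $U(0, \texttt{censor\_max})$ independent of survival, and
  observed time is the rounded-up minimum (whole days, at least 1).
  Because $z$ is a sum of indicators, its typical value is
  $\gamma K/2$ for $K$ planted pairs; the default baseline hazard is
  therefore calibrated as $\lambda_0 = 5\times 10^{-4}
  e^{-\gamma K/2}$ per day, pinning the *median-risk* patient at a
  median overall survival near 1400 days (realistic for lung
  adenocarcinoma cohorts) for any effect size, with roughly half of
  patients experiencing events under the default 10-year censoring
  window. An explicit `lambda0` overrides the calibration.
* **Covariates** (age, gender, stage, T/N/M, smoking) are drawn
  independently of survival, so they are exchangeable null covariates
  for calibration tests; `stage_beta` optionally adds
  $\beta_{st}(stage - 1)$ to the linear predictor for tests that need a
  second true prognostic factor.

`apply_monotone_distortion()` perturbs each sample with a random
strictly increasing transform (positive-slope affine, positive-exponent
power, or scaled log1p) and is the instrument for the package's central
invariance property: pair matrices and risk scores must be *exactly*
unchanged, and the tests assert bit-level equality.

What the generator does **not** emulate: TCGA's empirical FPKM
distribution, batch and purity structure, correlated co-expression
modules, non-proportional hazards, informative censoring, or realistic
mutation spectra. Passing tests therefore demonstrate correctness of
the machinery and statistical calibration under the stated model — not
clinical performance on real cohorts, which requires the external
validation workflow.

## Problem sizes used by the test suite

The suite checks planted-signature recovery on cohorts of 400 tumor
samples with 10 planted pairs at $\gamma = 0.8$ among a 60-gene panel
(several hundred retained noise pairs), averaged over 20 seeds, with
independent 300-sample validation cohorts regenerated from the stored
truth; null behaviour on 50 end-to-end runs at $\gamma = 0$ plus
200-replicate calibration loops for the log-rank and rank-sum tests;
and estimator oracles (hand-tabulated log-rank, uncensored ROC
reduction, `prior_df = 0` moderated t, exhaustive rank-sum enumeration)
on small fixed fixtures. These sizes give stable pass/fail behaviour
at seed-fixed reproducibility.

## Known limitations

* The time-dependent ROC implements the KM plug-in estimator only; the
  smoothed nearest-neighbour variant is not provided.
* Lasso-selected coefficients are penalized estimates; hazard ratios
  derived from them are conservative relative to an unpenalized refit
  (available via `refit = TRUE`).
* The identity filter and candidate statistics are computed on the
  retained tumor samples; cohorts assembled differently (e.g. filters
  computed before survival merging) can select slightly different pair
  sets.
* Published external benchmarks for the packaged signature (hazard
  ratios near 4.4 on the discovery platform and 1.6 on an independent
  microarray cohort) depend on the original full-size cohorts and
  unpublished tuning details; reproducing them requires those data and
  is outside the test suite's scope.
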