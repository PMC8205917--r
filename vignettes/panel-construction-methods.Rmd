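---
title: "Building serum miRNA diagnostic indices: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building serum miRNA diagnostic indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpanel)
```

## The problem

Circulating microRNAs measured by serum microarray are candidate
non-invasive markers for detecting early cancers. Given a case–control
cohort — a signal matrix of a few thousand miRNAs by a few thousand serum
samples, plus per-sample metadata — the goal is a small linear index over a
handful of miRNAs that separates cases from controls, together with honest
estimates of its operating characteristics on a held-out validation split.

`mirpanel` implements that workflow end to end: internal-control
normalization, robust expression filtering, Fisher linear discriminant
analysis (LDA) grown by greedy forward search under leave-one-out
cross-validation (LOOCV), model-size selection by paired DeLong tests,
Youden-index recentring of the cutoff, and a full validation report.

## Preprocessing

**Normalization.** Microarray fluorescence carries a sample-wide
multiplicative technical factor (input amount, labelling, scanning). Each
sample is rescaled so that the arithmetic mean of three designated
internal-control miRNAs equals a fixed reference level. The reference is
the grand mean of per-sample control means, estimated **once on the
discovery split** and frozen (`fit_normalization()`); validation and any
later cohort are rescaled to the same level. Freezing prevents information
leaking from validation into the model, and keeping values on the raw
signal scale preserves the meaning of the filter threshold below.

**Control stability.** Before trusting the controls, `control_stability()`
computes a geNorm-style M statistic: for control $j$, the mean over the
other controls $k$ of the across-sample standard deviation of
$\log_2(x_j/x_k)$. M is invariant to the sample-wide factor; values above
about 1 indicate an unstable control and trigger a warning in
`run_discovery()`.

**Robust filter.** A miRNA is retained when its normalized signal is
strictly above 64 in strictly more than 50% of samples, in the case group
and in the control group (`group_rule = "each_group"`; `"any_group"` is
available because "in each group" admits both readings). Both inequalities
are strict, following the rule's wording ("exceeding", "more than"). The
internal controls are excluded from candidacy.

**Feature scale.** Models are fitted on $\log_2(\max(x, 1))$ of the
normalized signal. Whether published index coefficients apply to log or
linear signal is generally not stated in print; the fitted model therefore
carries an explicit `feature_scale` tag (scale + control ids + frozen
reference level), and `apply_index()` refuses a matrix whose scale tag
does not match. The floor at 1 bounds the influence of values near the
detection floor.

## The discriminant engine

For panel features $x$ with class means $\mu_1, \mu_0$ and pooled
within-class covariance $S$ (denominator $n-2$), Fisher LDA scores
$w^\top x + b$ with $w = S^{-1}(\mu_1 - \mu_0)$ and midpoint intercept
$b = -w^\top(\mu_1+\mu_0)/2$. A singular $S$ (e.g. duplicated features)
falls back to a ridge ($10^{-8}\,\mathrm{tr}(S)/p$ on the diagonal) with a
warning; the perturbation is far below estimation noise for
well-conditioned fits.

**LOOCV.** The search criterion is leave-one-out accuracy at the midpoint
cutoff 0. Each fold is obtained from the full fit by a Sherman–Morrison
rank-one downdate of the pooled scatter, vectorized over held-out samples,
so a panel's LOOCV costs $O(np^2)$ rather than $n$ refits; degenerate
folds fall back to an explicit refit. The unit tests pin this path to a
brute-force per-fold oracle exactly. Youden recentring is applied only to
the final model, not per fold — the cheaper midpoint rule is used inside
the search.

**Greedy forward search.** The size-1 panel is the candidate with the best
LOOCV accuracy; size $k$ adds the candidate maximizing the accuracy of the
union. No swaps or backtracking. Ties fall to higher in-sample AUC, then
to the lexicographically smaller miRNA id, making the search deterministic
and invariant to candidate order.

**Model size.** For each consecutive pair of panel sizes the trace records
a paired DeLong test on the in-sample scores and a Pearson
$\chi^2$ comparison of the LOOCV accuracies. Selection uses the DeLong
rule: the largest $k$ whose step from $k-1$ is significant
(two-sided, $\alpha = 0.05$) while the step to $k+1$ is not; if no size
qualifies, $k = 1$. The $\chi^2$ p-values are reported but not used to
select — the DeLong criterion is the stated decision rule for the
four-versus-five comparison this package models its selection on. No
multiplicity correction is applied anywhere; nested p-values are reported
raw.

**Cutoff.** The Youden threshold $t^\*$ maximizes
$J = \text{sensitivity} + \text{specificity} - 1$ over the observed
training scores (classify positive at score $\ge t$); among ties the
smallest threshold wins, maximizing sensitivity — the natural bias for a
screening test. The intercept is shifted by $t^\*$ so the operating cutoff
is exactly 0, and a score exactly at the cutoff is classified as a case.

## Inference

AUCs use the midrank Mann–Whitney estimator; variances and the paired test
come from DeLong's per-observation structural components, with two-sided
normal p-values and 95% CIs clipped to $[0,1]$. Sensitivity, specificity
and accuracy get Wald intervals $p \pm 1.96\sqrt{p(1-p)/n}$, clipped —
this reproduces printed intervals of the kind (0.974–0.993) for 696/708.
Predictive values at a screening prevalence $\pi$ are the Bayes
identities $\mathrm{PPV} = \mathrm{se}\,\pi / (\mathrm{se}\,\pi +
(1-\mathrm{sp})(1-\pi))$ and $\mathrm{NPV} = \mathrm{sp}(1-\pi) /
(\mathrm{sp}(1-\pi) + (1-\mathrm{se})\pi)$; the default prevalence 0.742%
is a published gastric-cancer screening figure. Confidence intervals for
PPV/NPV are out of scope (no standard method is implied by the numbers
this mirrors). Baseline balance between arms uses pooled-variance t-tests
for age and Pearson $\chi^2$ (no continuity correction) for categorical
covariates.

## The synthetic cohort generator

No real microarray data ship with the package; `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes, so
every downstream stage is testable. Per sample, the log2 biological signal
of miRNA $m$ is

$$\text{baseline}_m + \text{effect}_m\,[\text{case}] +
  \text{batch}(source) + \lambda_m Z + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_m^2 - \lambda_m^2),$$

exponentiated, clipped below at the detection floor (8, far under the
filter threshold 64 so filtering is exercised, not saturated), and then
multiplied by a sample-wide lognormal technical factor (sd 0.3 in log2)
that normalization must — and does, exactly — remove. Lognormal signals
are the standard model for fluorescence intensities. Filler baselines are
uniform on log2 $[2, 10]$, so roughly half the miRNAs fail the robust
filter; three internal controls sit at baseline 10 with sd 0.05. Because
residual noise is $\sigma_m^2 - \lambda_m^2$, every marker's *marginal*
log2 sd is $\sigma_m = 1$ and its marginal AUC follows the closed form
$\Phi(\text{effect}/(\sigma\sqrt{2}))$ regardless of latent coupling — the
property tests rely on this.

**Planted markers.** The default panel plants four markers: up +1.6, down
−1.2, moderate +0.8 log2 units, and a *suppressor* with effect 0. The
suppressor shares a latent per-sample nuisance factor with the up-marker
(loading 0.9 on both, marginal correlation 0.81). Marginally the
suppressor is useless (AUC ≈ 0.5), but a multivariate discriminant uses it
to cancel the shared noise: the pair's Mahalanobis separation is
$e^2/(1-\lambda^4) \approx 7.4$ versus $e^2 = 2.56$ for the up-marker
alone. This is the mechanism by which a near-chance miRNA raises a panel's
AUC. The loading was calibrated (over a 20-seed sweep of 0.80–0.93) as the
strongest coupling at which greedy search still recovers at least three of
the four planted markers in ≥ 80% of seeds at 200 samples/group among 300
miRNAs, while the selected model's LOOCV accuracy (≈ 0.91–0.95) sits near
the operating point of strong published serum panels.

**Covariates.** Cases and controls draw age (normal, mean 65, sd 11,
truncated to 20–90) and gender (72% male) from identical distributions —
matching is emulated distributionally, not by explicit pairing — and
covariates do not enter the signal model. Controls split across three
sources (35.1/32.7/32.2%) with small per-source batch shifts (−0.2, 0,
+0.2 log2); being sample-wide, these are removed by normalization, which
is deliberate: no batch-correction method is in scope. Case stage and
histology follow the proportions 95.2/4.1/0.7% (IA/IB/II) and
56.4/42.2/1.4%.

**Splitting.** `split_discovery_validation()` stratifies by group and by
control source within controls, using largest-remainder rounding with
seeded tie-breaks: every stratum lands within one sample of the exact
ratio and arm totals hit floor/ceiling of $n \times$ ratio, so 1417 + 1417
at 1:1 gives arms of 708 + 709 and 709 + 708.

**What the generator does not emulate.** Real serum cohorts have
heavy-tailed and miRNA-correlated noise beyond one latent factor,
miRNA-specific batch responses that a sample-wide rescaling cannot remove,
covariate-linked expression (age, gender, H. pylori status, smoking), and
chip-level spatial artefacts. Passing tests therefore demonstrate the
*machinery* — recovery of planted structure, leak-free validation, correct
inference — not performance on any real cohort.

## Numerical and degenerate-input choices

* Boundary classification: score = cutoff ⇒ case (screening favours
  sensitivity).
* Strict inequalities in the robust filter; exactly 50% above threshold
  fails.
* LOOCV folds with a singular scatter or a vanishing Sherman–Morrison
  denominator fall back to explicit refits; a singular full-data scatter
  routes the whole panel through the brute-force path.
* DeLong with both variances degenerate: equal AUCs give $p = 1$;
  a zero-variance nonzero difference gives $p = 0$.
* Zero-variance miRNAs are dropped (with a warning) before clustering/PCA;
  constant ages short-circuit the balance t-test to $p = 1$.
* `select_model_size()` treats a missing p-value as non-significant.

## Clustering and PCA summaries

For the final panel, samples are clustered agglomeratively on Pearson
dissimilarity ($1 - r$ across the per-miRNA-standardized features) with
Ward linkage (`ward.D2`), cut at two clusters, and scored by
best-permutation agreement with the true labels. PCA reports per-component
explained-variance fractions of the standardized features (correlation
PCA) and the first three coordinates. With a strongly coupled
suppressor pair in the panel, the shared nuisance direction competes with
the case–control contrast under a correlation metric, so agreement on the
default synthetic cohort is around 0.75–0.9 — a property of
correlation-based clustering on few features, not a defect; cleanly
separated configurations cluster at agreement ≥ 0.9.

## Problem sizes used in the shipped checks

Unit and property tests run on cohorts of 20–200 samples/group with 10–100
miRNAs; the parameter-recovery suite uses 20 seeds at 200/group among 300
miRNAs; `scripts/acceptance.R` runs the full pipeline once at study scale
(1417 + 1417 samples, 2565 miRNAs). These sizes were chosen so the whole
suite exercises every code path, including the study-scale shapes.

## Worked example

```{r example, message = FALSE}
cfg <- cohort_config(n_case = 200, n_control = 200, n_mirna = 300, seed = 42)
cohort <- generate_cohort(cfg)
samples <- split_discovery_validation(cohort$samples, 0.5, seed = 42)
fit <- run_discovery(cohort$expression, samples, cfg$control_mirna_ids)
tidy(fit)[, c("k", "added", "accuracy", "auc", "p_auc_vs_prev")]
report <- run_validation(fit, cohort$expression, samples)
glance(report)
```
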