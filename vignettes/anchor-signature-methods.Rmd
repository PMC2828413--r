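---
title: "Anchor-gene signatures: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene signatures: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorsig)
```

## The analysis in one paragraph

`anchorsig` implements a family of prognostic-signature analyses built
around a single *anchor gene* — a gene (S100A8 in the motivating
application, non-muscle invasive bladder cancer) whose expression is
believed to track disease progression. Instead of relying on the anchor
alone, the analysis (i) screens the whole transcriptome for genes whose
expression correlates with the anchor, (ii) clusters patients on that
correlated-gene signature into a high-anchor cluster (HSC) and a
low-anchor cluster (LSC), (iii) asks whether cluster membership can be
predicted by standard class-prediction machinery under honest
cross-validation, and (iv) asks whether cluster membership predicts
time to progression after adjusting for routine clinicopathologic
covariates. The package adds a synthetic-cohort generator with a known
two-cluster structure so that every stage — and the statistical claims
behind it — can be exercised and audited without access to microarray
repositories.

## Preprocessing

Expression values are assumed to be log2-scale intensities, features in
rows and samples in columns. `quantile_normalize()` forces every sample
onto the common distribution given by the across-sample mean of sorted
vectors; tied values within a sample receive the mean of the reference
values at their tied ranks (this is the convention implemented by
`limma::normalizeQuantiles(ties = TRUE)`, which the function wraps).
`log2_median_center()` then subtracts each feature's median and then
each sample's median, one pass each in that order. A single pass is a
deliberate choice: "centering across genes and samples" is ambiguous
between one sweep and iterating to convergence (Cluster 3.0 offers
both), and one ordered sweep is reproducible, fast, and leaves every
sample with an exactly zero median — only the *last* pass's zero is
guaranteed, and the tests assert exactly that. Missing values are
rejected by the readers rather than imputed.

## Deriving the signature

`median_dichotomize()` splits samples at the anchor's median; values
strictly above the median are "high", so with an odd cohort the
median-tied sample joins the low group (103 samples split 52/51). This
tie rule is one of several places where the package fixes a convention
that the underlying methods literature leaves open; every such rule is
deterministic and documented on the function.

`pearson_screen()` correlates each non-anchor feature with the anchor
across **all** samples (not within the dichotomized groups) and keeps a
feature when both criteria hold: two-sided p below `alpha` (default
0.001, from t = r·sqrt((n−2)/(1−r²)) on n−2 df) and |r| above
`r_threshold` (default 0.3). At n ≈ 100 the p criterion is the binding
one; at large n the |r| criterion prevents the signature from absorbing
trivially small correlations. The anchor itself is excluded from the
screen but always heads the signature list, because the downstream
clustering is defined over "the anchor and its correlated genes". No
multiplicity correction is applied: the screen is intentionally a raw
per-feature filter, and the honest error control happens downstream in
cross-validation and survival testing.

## Two clusters of patients

Samples are clustered on the signature features with the Eisen
conventions: *uncentered correlation* similarity
s(x,y) = (1/n)·Σ (x_i/σ⁰_x)(y_i/σ⁰_y), where σ⁰ is the root mean
square about zero rather than about the mean — appropriate for
median-centered data where zero is a meaningful reference level — and
average linkage (UPGMA) agglomeration. `average_linkage()` is written in
the package rather than delegated to `stats::hclust` for one reason:
exact distance ties are broken lexicographically by cluster creation
order, making merge sequences fully deterministic and testable against a
brute-force re-averaging oracle. Heights are not forced to be monotone;
average linkage on correlation distances can legitimately invert.

The two patient groups are obtained by removing the root merge
(`cut_two()`), not by a height threshold: the method calls for exactly
two groups and the root split is the unique parameter-free way to get
them. The cluster with the higher mean anchor expression is labelled
HSC; an exact tie in means is refused rather than silently resolved,
since it indicates the anchor does not distinguish the clusters at all.

## Class prediction under LOOCV

Five classifiers are implemented over t-test-selected features
(`select_features()`, pooled-variance t, p < 0.001, ordered by p then
|t| then identifier):

* **CCP** — compound covariate predictor: score c_j = Σ t_i·x_ij with
  the training t statistics as weights, threshold at the midpoint of the
  class-mean scores.
* **BCC** — the same score with Gaussian class-conditional densities
  (pooled variance, equal priors — the priors are a package choice, the
  classical description does not state them) and posterior-probability
  classification.
* **DLDA** — diagonal linear discriminant analysis: per-class means and
  pooled per-feature variances. The diagonal (rather than full
  covariance) variant is chosen deliberately: with p ≫ n a full
  covariance is singular, and diagonal LDA is the standard
  class-comparison variant in this regime.
* **NC** — nearest Euclidean centroid.
* **SVM** — linear soft-margin SVM at C = 1 without rescaling (via
  `e1071::svm`); kernel and cost are fixed because the classical
  framework treats the SVM as a fixed recipe, not a tuned model.

`loocv()` repeats the *entire* model-building procedure — feature
selection included — inside every fold, so the held-out sample cannot
leak into its own prediction. This is the methodological heart of the
validation design, and it is enforced by a dedicated audit: perturbing a
held-out sample's values must leave that fold's selected features and
fitted parameters bit-identical, for every method. A fold whose training
set yields no significant feature is recorded as failed and predicted as
the training majority class rather than aborting the run.

Ties at every decision boundary are deterministic: a score exactly at
the CCP threshold goes to the class with the lower mean score, a BCC
posterior of exactly 0.5 and exact DLDA/NC distance ties go to class 1
(HSC). Reports follow the sensitivity/specificity/PPV/NPV layout with
each class in turn treated as positive; undefined ratios are reported as
missing, never as zero. An optional tuning of the selection threshold
(grid over alpha) is *not* performed by default: with in-fold selection
the default 0.001 already yields stable signatures, and a tuned alpha
would complicate the leakage audit without changing the conclusions the
package tests.

## Survival analysis

`km_fit()`, `logrank_two_group()` and `cox_fit()` wrap the
`survival` package (Kaplan-Meier product-limit with Greenwood variance;
the standard log-rank statistic; Cox partial likelihood with the Efron
tie correction, Newton-Raphson to a 1e-9 score tolerance, at most 50
iterations). Efron ties matter here: follow-up recorded in months ties
heavily, and Breslow's approximation degrades faster. Confidence
intervals are Wald intervals exp(β ± 1.96·SE) — the asymmetric CIs
typical of such reports. Monotone likelihoods (e.g. every progression
event in one cluster, a real possibility with ~11 events) are flagged
as non-converged with the diagnostic preserved instead of being hidden
behind a huge finite estimate; collinear covariates raise an error
naming the columns. `cox_progression()` fixes the reference levels of
the clinical covariates (stage Ta, grade low, single tumor, size ≤ 3 cm,
no intravesical therapy, LSC) so the output table has a stable, familiar
shape.

Two identities anchor the implementation and are asserted to 1e-9 in the
tests: the Cox score statistic at β = 0 for a single binary covariate
equals the log-rank chi-square on tie-free data, and the Kaplan-Meier
estimate equals one minus the empirical CDF when nothing is censored.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` draws, per sample, a latent cluster
z ~ Bernoulli(`cluster_prob`), an anchor value
N(`anchor_means[z]`, `anchor_sd`²), module features
β_g·(a − mean(anchor_means)) + noise with |β_g| uniform on
`module_loading_range` and a fixed share of negative signs, independent
N(0,1) background features, progression times
Exponential(`baseline_hazard`·`hazard_ratio`^z) censored by
Uniform(0, `censor_horizon`), and clinical covariates drawn per-cluster
from `covariate_spec`. Module features are driven by the *centered
anchor signal* rather than by the cluster label directly, so the
anchor-module correlation is controlled analytically:
r = β·σ_a / sqrt(β²·σ_a² + σ_noise²) with σ_a the marginal anchor SD.
Everything flows from one seed; the same seed reproduces the cohort
exactly.

Defaults are fixed once to describe the cohort scale the analysis was
designed for: 103 samples; 2,000 features of which 1,000 form the
correlated module (mirroring a ≈1,000-gene signature); cluster
probability 0.49 (a ≈50/53 split — the split sizes are inferred from
report arithmetic, not stated, and are treated as a plausible default);
anchor means −1 and +1 with SD 0.5 (a 4-SD separation, comfortably
above the 2-SD floor at which cluster recovery is still expected);
hazard ratio 8 between clusters; censoring horizon 137 months (the
maximum follow-up of the motivating cohort); and a baseline hazard of
3.9994×10⁻⁴ per month solved analytically so the expected event
fraction is exactly 10.7% — the motivating cohort's progression rate
(11/103). `expected_event_fraction()` exposes the closed form
P(event) = 1 − (1 − e^{−λτ})/(λτ), mixed over clusters. Covariates are
independent of survival given the cluster by default, which makes the
signature the only prognostic factor — the configuration in which Cox
recovery is cleanly interpretable.

What the generator does **not** emulate: probe-level artifacts, batch
effects, platform differences between cohorts, non-proportional
hazards, informative censoring, or covariates that genuinely confound
the signature. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's statistics behave as designed under the assumed
model — not that any particular real signature is valid. In particular
the independent "test cohort" here is a second draw from the same
generative model; cross-platform transfer of a real signature is a
harder problem that the package deliberately leaves out of scope, along
with pathway/network enrichment and probe-to-gene annotation.

## Numerical and design notes

* Problem sizes in the test suite are chosen to keep a full run at desk
  scale: oracle comparisons use ≤ 20 features × ≤ 10 samples, coverage
  uses 500 replicates at n = 300, type-I control uses 1,000 replicates
  at n = 80, and the end-to-end check uses the full default cohorts
  (train 103, test 302).
* Zero-variance features are excluded from the correlation screen with
  a logged count (their r is undefined), dropped with a warning in DLDA,
  and produce the documented degenerate t-test results (t = 0, p = 1
  for equal means; p = 0 flagged for unequal means).
* The uncentered-correlation distance is clamped to [0, 2] against
  floating-point drift; an all-zero sample vector is an error naming the
  sample, since its direction is undefined.
* `run_pipeline()` writes no timestamps into its outputs, so a config
  plus seed reproduces the bundle byte for byte; stage failures
  propagate with the stage name and partial outputs are retained.
* Cluster-label prediction on the simulated *test* cohort is scored
  against that cohort's true latent clusters; on real data one would
  instead compare against a re-derived clustering, which
  `run_pipeline()` does when the test cohort comes from files.

## Known limitations

The screen's raw p-threshold is not a false-discovery control and is not
meant to be one. The two-cluster root split can produce very unbalanced
groups on weakly structured data, and LOOCV then refuses to run (a class
needs at least 3 members). With ~11 events, the multivariate Cox model
is intentionally fragile — wide intervals and occasional monotone
likelihoods are faithful reflections of the design, and the package
surfaces them rather than smoothing them away.
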