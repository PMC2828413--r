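# anchorsig

Anchor-gene expression signatures for disease-progression prognosis.

## The problem

In non-muscle invasive bladder cancer (NMIBC), a minority of patients
progress to muscle-invasive disease, and routine stage/grade pathology
predicts that progression poorly. One line of attack starts from a single
*anchor gene* with suspected prognostic value — S100A8 is the motivating
example — and widens it into a molecular signature: the set of genes whose
expression correlates with the anchor across the cohort. `anchorsig`
implements that whole analysis as a tested, reusable R pipeline, for
statisticians and computational biologists who want to derive, validate and
stress-test anchor-based signatures:

1. **Preprocess** — quantile normalization and log2/median centering
   (`quantile_normalize()`, `log2_median_center()`).
2. **Derive** — Pearson screen of every feature against the anchor,
   keeping features with *p* < 0.001 and |*r*| > 0.3
   (`pearson_screen()`); median dichotomization of the anchor is also
   available (`median_dichotomize()`).
3. **Cluster** — Eisen-style hierarchical clustering of samples on the
   signature features (uncentered correlation similarity, average
   linkage), cut at the root into a high-anchor cluster (HSC) and a
   low-anchor cluster (LSC) (`uncentered_correlation_distance()`,
   `average_linkage()`, `cut_two()`).
4. **Validate** — five classifiers (compound covariate predictor,
   Bayesian compound covariate, diagonal LDA, nearest centroid, linear
   SVM) predict cluster membership under leave-one-out cross-validation
   with gene selection repeated *inside every fold*, plus
   independent-cohort prediction (`loocv()`, `validate_classifiers()`);
   results are reported as per-class sensitivity/specificity/PPV/NPV.
5. **Survival** — Kaplan–Meier curves, the two-group log-rank test, and a
   multivariate Cox proportional-hazards model (Efron ties) of the
   signature against stage, grade, tumor count, size and intravesical
   therapy (`km_fit()`, `logrank_two_group()`, `cox_progression()`).

The core statistics, in the field's notation: the compound covariate of a
sample *j* is *c<sub>j</sub>* = Σ<sub>i</sub> *t<sub>i</sub>x<sub>ij</sub>*
over the selected genes, with *t<sub>i</sub>* the two-sample pooled-variance
t statistics; uncentered correlation is
*s(x,y)* = (1/n)Σ(*x<sub>i</sub>*/σ⁰<sub>x</sub>)(*y<sub>i</sub>*/σ⁰<sub>y</sub>)
with σ⁰ the RMS about zero; the log-rank statistic is
(Σ(O₁ᵢ−E₁ᵢ))²/ΣVᵢ with hypergeometric variances; the Cox model maximizes
the Efron-corrected partial likelihood by Newton–Raphson.

Because the original microarray cohorts live in external repositories, the
package ships a first-class synthetic-cohort generator
(`simulate_cohort()`): a latent two-cluster structure drives the anchor, a
~1,000-feature correlated module (both signs), background noise features,
cluster-dependent exponential progression hazards with uniform censoring,
and clinical covariates. Defaults emulate the motivating study scale: 103
samples, an expected 10.7% progression fraction over 137 months, and a
≈50/53 cluster split. See the methods vignette
(`vignettes/anchor-signature-methods.Rmd`) for the model, every tunable
parameter, and what the generator deliberately does not emulate.

## Worked example

```r
library(anchorsig)

cohort <- simulate_cohort(sim_config(seed = 1L))
expr   <- log2_median_center(quantile_normalize(cohort$expression))

screen <- pearson_screen(expr, "S100A8")
screen
#> correlation_screen: anchor S100A8 | 2000 features screened, 902 selected (p < 0.001, |r| > 0.3)

clusters <- cut_two(average_linkage(
  uncentered_correlation_distance(expr[screen$signature, ])), expr, "S100A8")
clusters
#> cluster_assignment: HSC = 50 samples (mean anchor 0.9544 ), LSC = 53 samples (mean anchor -0.6493 )

logrank_two_group(cohort$clinical$time_months, cohort$clinical$event, clusters$labels)
#> log-rank test: chi-square = 5.9707 on 1 df, p = 0.01455
#>  group  n observed expected
#>    HSC 50       12 7.147337
#>    LSC 53        4 8.852663

cox_progression(cohort$clinical, clusters$labels)
#> Cox proportional-hazards fit (Efron ties), converged in 5 iterations
#>                  term            HR (95% CI)          p
#>              stage_T1  0.572 (0.182 - 1.796) 0.33887412
#>            grade_high  1.905 (0.549 - 6.611) 0.31005992
#>         n_tumors_2to7  2.110 (0.680 - 6.552) 0.19639098
#>          n_tumors_ge8 2.686 (0.540 - 13.369) 0.22761147
#>            size_gt3cm  2.670 (0.889 - 8.019) 0.07998190
#>  intravesical_therapy  0.820 (0.284 - 2.371) 0.71436257
#>         signature_HSC 5.353 (1.589 - 18.037) 0.00679488

loocv("ccp", expr, clusters$labels)
#> cv_result (CCP): 103 folds, accuracy 0.9903
#>      predicted
#> truth HSC LSC
#>   HSC  50   0
#>   LSC   1  52
```

Reading the output: 902 of 2,000 screened features correlate with the
anchor past both thresholds; root-split clustering of the signature
separates 50 HSC from 53 LSC patients; HSC patients progress faster
(log-rank p = 0.015), the signature is the strongest covariate in the
multivariate Cox model (HR 5.4, 95% CI 1.6–18.0) — note the wide interval,
typical of a cohort with 16 events — and the compound covariate predictor
recovers cluster membership in 102/103 leave-one-out folds.

`run_pipeline(pipeline_config(...), outdir)` chains all stages and writes
`signature.tsv`, `clusters.tsv`, `metrics.tsv`, `cox_table.tsv`,
`km_curves.tsv` and a run log; the bundle is byte-reproducible from config
plus seed. A shell wrapper lives at `inst/scripts/run_pipeline.R`.

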