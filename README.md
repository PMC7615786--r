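# endorisk

Multigene recurrence risk scores from endocytic gene dysregulation in
radioiodide-treated papillary thyroid cancer.

## The problem

Radioiodide (RAI) therapy only works while the sodium/iodide symporter
(NIS) is at the tumour cell's plasma membrane; endocytosis pulls it away.
Tumours with broadly dysregulated endocytic gene expression (the AP2
adaptor genes and their co-regulated partners) respond poorly to RAI and
recur more often. `endorisk` is for biostatisticians and computational
biologists who want to turn that observation into a testable prognostic
pipeline: given a genes × samples log2 expression matrix and a clinical
table with disease-free survival (DFS), it builds and evaluates a
count-based multigene recurrence risk classifier, and it ships a synthetic
cohort generator with planted ground truth so every stage can be validated.

## The method

For gene *g* with ROC-oriented cutpoint *c<sub>g</sub>* (Youden-optimal
against recurrence, orientation `high_is_risk`/`low_is_risk` frozen at
training), patient *i* receives a dysregulation call

> d<sub>ig</sub> = 1{ x<sub>ig</sub> strictly beyond c<sub>g</sub> on the risk side }.

Patients are clustered on their call profiles (Hamming distance, Ward
linkage; 4 major clusters, 14 nested subclusters). With target subcluster
*T* (highest recurrence) and reference clusters *R₁*, *R₂* (lowest
recurrence), each gene's cluster-frequency contrast is

> ΔEG(g) = ½ [ (f<sub>T</sub>(g) − f<sub>R₁</sub>(g)) + (f<sub>T</sub>(g) − f<sub>R₂</sub>(g)) ],

and genes with mean ΔEG ≥ 0.3 are panel candidates. The risk score is the
plain count S<sub>i</sub> = Σ<sub>g∈panel</sub> d<sub>ig</sub>, with the
panel size chosen by 5-fold event-stratified cross-validated AUC and the
high/low threshold Youden-optimal on training scores. Evaluation reports
AUC, Kaplan–Meier curves with log-rank tests, and univariate plus
multivariate Cox proportional-hazards models (Efron ties, Wald 95% CIs)
adjusting for age > 50, sex, stage III+IV, T3+T4 and N1.

See `vignettes/endorisk-methods.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

```r
library(endorisk)

# training cohort: 500 patients, 137 endocytic genes, 10 planted risk genes
cohort <- generate_cohort(simulation_config(seed = 7))
cohort
#> <endorisk_cohort> 500 patients, 137 genes, 10 risk genes, 4 clusters; 71 events (86% censored)

fit <- run_pipeline(cohort$expression, cohort$clinical, seed = 7)
fit$classifier
#> <risk_classifier> 30-gene panel, high risk at score >= 11 (training cohort n500-e71)
fit$classifier$cv
#>   panel_size    cv_auc
#> 1         10 0.8462768
#> 2         20 0.8708065
#> 3         30 0.8731037
#> 4         34 0.8651104

# independent validation cohort from the same gene population
validation <- generate_cohort(simulation_config(seed = 50007))
calls <- call_dysregulation(validation$expression, fit$cutoffs)
evaluate_classifier(fit$classifier, calls, validation$clinical)
#> <classifier_evaluation> n = 500 (76 events), 156 high risk
#>   AUC (score) 0.847 | AUC (label) 0.766 | log-rank p 1.67e-24
#>   median DFS high risk: 10.69 months
#>   multivariate HR (high vs low) 10.767 (95% CI 6.281-18.455), p = 5.48e-18

# how many planted risk genes made the panel?
length(intersect(fit$classifier$panel$gene_id, cohort$truth$risk_gene_ids))
#> [1] 10
```

Reading the output: the pipeline screened the 137 genes down to the
recurrence-relevant subset, chose a 30-gene panel by cross-validated AUC
(0.873), and — on a cohort it never saw — the count score separates
recurrence with AUC 0.847, a median DFS of 10.7 months in the high-risk
group, and a multivariate hazard ratio of 10.8 after adjusting for age,
sex, stage, T and N stage. All 10 hazard-carrying genes planted by the
generator were recovered in the panel.

Real cohorts are read with `read_expression()` / `read_clinical()` /
`read_gmt()`; `filter_cohort()` reproduces subgroup analyses (BRAF-like,
RAI-treated, BRAF-mutant and their complements).

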