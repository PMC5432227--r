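# mpathscore

Pathway activity scoring and heterogeneity analysis for tumour
transcriptomes.

Bulk expression cohorts of solid tumours — prostate cancer prominently —
show marked *inter-tumour metabolic heterogeneity*: the same pathway
(glycolysis, one-carbon metabolism, proline degradation, choline
metabolism, ...) can be strongly up in some tumours and down in others.
`mpathscore` implements the analysis used to quantify that heterogeneity
from curated pathway gene sets and relate it to outcome:

1. **Normalize** expression: quantile normalization for array intensities,
   median-of-ratios size factors (plus `log2`) for RNA-seq counts.
2. **Score** each sample on each pathway. For gene *g* and sample *s*,

   z(g, s) = (x(g, s) − mean_ref(g)) / sd_ref(g)

   with the reference population either *all tumours of the cohort*
   (xenograft-panel style: scores read as deviation from the tumour
   average) or the *benign samples* (tumour-vs-normal cohorts). The
   pathway score is the arithmetic mean of z over the pathway's measured
   genes — a location/scale-free summary in reference-SD units.
3. **Test** tumour vs benign pathway activity: two-sample Wilcoxon
   rank-sum on per-sample scores (exact enumeration for small samples;
   pathways with fewer than 6 measured genes are not rank-tested) and
   Welch *t* on per-sample mean log2 expression.
4. **Cluster** the samples-by-pathways score matrix (agglomerative,
   deterministic tie-breaking, Newick export) to display heterogeneity
   and check that matched sample pairs co-segregate.
5. **Stratify survival** by pathway outliers: a tumour whose
   benign-re-standardized score exceeds ±2 SD (strict) is an outlier;
   outlier vs rest biochemical-recurrence-free survival is compared by
   Kaplan–Meier curves with Mantel-Cox and Gehan–Breslow (at-risk
   weighted) log-rank tests, all implemented from their counting-process
   formulas. Spearman rank correlation against ordinal stage is included.

A synthetic-cohort generator (`simulate_cohort`, `simulate_pairs`,
`simulate_survival`) produces cohorts with the statistical structure the
analysis assumes — benign/tumour groups, pathway-coherent subgroup shifts,
correlated matched pairs, outlier-dependent exponential hazards with
independent censoring — so every stage is testable without
controlled-access data. A reconstructed 23-pathway metabolic catalog ships
as `inst/extdata/metabolic_pathways_23.synthetic.gmt` (gene memberships are
a documented synthetic stand-in, assembled from standard pathway
references).

## Worked example

A synthetic benign-referenced cohort (28 benign / 112 tumours) with a
2-SD shift planted on the 10-gene pathway `SYNP01` in 25% of tumours, and
an outlier hazard ratio of 3:

```r
library(mpathscore)
cfg <- synthetic_config(
  n_benign = 28, n_tumour = 112, n_genes = 33,
  effects = list(SYNP01 = list(delta = 2, fraction = 0.25)),
  hazard_ratio = 3, seed = 7)
sim <- simulate_survival(simulate_cohort(cfg), "SYNP01")

z  <- zscore(sim$matrix, sim$annotations, scheme = "benign")
sc <- pathway_scores(z, cfg$catalog)
res <- wilcoxon_pathway_test(sc, sim$annotations)
res[, c("pathway", "p_value", "direction", "n_genes")]
#>   pathway p_value   direction n_genes
#> 1  SYNP01  0.0256 upregulated      10
#> 2  SYNP02  0.9067          ns      10
#> 3  SYNP03  0.2179          ns       8
#> 4  SYNP04      NA  not tested       5

oc   <- flag_outliers(sc, sim$annotations, threshold_sd = 2)
sdat <- stratify_by_outlier(oc, "SYNP01", "up", sim$annotations)
logrank_test(sdat, "mantel_cox")$p_value
#> 0.00146
logrank_test(sdat, "gehan_breslow")$p_value
#> 0.000374
```

Reading the output: the planted pathway is the only one called
(`p = 0.026`, upregulated; the 5-gene `SYNP04` is below the 6-gene floor
and reported `not tested`). 32 tumours exceed +2 benign-SD on `SYNP01`
(the 28 truly affected plus noise-edge cases), and their recurrence-free
survival is significantly worse than the remaining 80 tumours under both
log-rank weightings.

The same flow runs from files (`read_expression`, `read_annotations`,
`load_gmt`) or end-to-end via `run_pipeline(run_config(...))`, which
writes scores, the test table, outlier calls, Newick dendrogram, KM
curves and a `summary.json` into a run directory. A thin CLI wrapper
lives at `inst/cli/pipeline.R`.

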