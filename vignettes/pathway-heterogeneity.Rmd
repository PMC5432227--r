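---
title: "Pathway scores, outliers, and survival: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway scores, outliers, and survival: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpathscore)
```

## The model

`mpathscore` treats pathway activity as a location statistic on
standardized expression. Given a gene-by-sample matrix on a roughly
log-normal continuous scale (quantile-normalized array intensities, or
size-factor-normalized log2 counts), and a reference population *R* of
samples, each gene is standardized by its reference moments,

$$z_{gs} = \frac{x_{gs} - \bar{x}_{gR}}{s_{gR}},$$

and a pathway's score in sample *s* is the mean of $z_{gs}$ over the
pathway's measured genes. The score answers: *averaged over this gene
set, how many reference SDs does this sample sit away from the reference
mean?* Two reference schemes serve two designs:

* **cohort** — *R* = all tumour samples of the cohort. Appropriate when
  there is no normal-tissue arm (e.g. a xenograft panel); the heatmap of
  scores then displays inter-tumour heterogeneity around the tumour
  average, and reference-sample scores average exactly 0 per pathway.
* **benign** — *R* = the benign samples. Appropriate for tumour-vs-normal
  cohorts; scores read as deviation from normal tissue, and benign
  scores average exactly 0.

Assumptions worth stating: genes enter unweighted (no topology, no
stoichiometry); effects are taken additive on the log scale, so the
z-score machinery is sensitive to location shifts; a pathway score is
meaningful only through its measured genes — the catalog is intersected
with the matrix and per-pathway coverage is reported.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_testable_genes` | 6 | genes | sets with fewer than 6 measured genes are excluded from rank testing; averaging so few z-scores leaves the score dominated by single genes |
| `threshold_sd` | 2 | benign score-SD | outlier cut, strict inequality on both sides (a score exactly at ±2 is `none`) |
| `alpha` | 0.05 | — | direction calls (`upregulated`/`downregulated`) are made only below this level; raw p-values by default, Benjamini–Hochberg available via `adjust = "BH"` |
| `pseudocount` | 1 | counts | for `log2_transform` of normalized counts |
| clustering `distance`, `linkage` | euclidean, average | — | the usual defaults for signature heatmaps; `correlation` distance and `complete`/`ward`/`single` linkage are exposed because the choice is genuinely open (see below) |
| `horizon` | none | months | optional administrative censoring, e.g. 60 for a 5-year analysis |

## The outlier scale

"More than 2 SD relative to controls" under-determines *whose* SD. A raw
pathway score is a mean of $m$ z-scores, so for roughly independent genes
its SD is near $1/\sqrt{m}$, not 1 — a raw ±2 cut would flag almost
nothing regardless of biology. `flag_outliers` therefore re-standardizes
each pathway's scores by the *benign samples' score mean and SD*
(`restandardize_scores`) before applying the strict ±2 cut: the benign
distribution is the yardstick the "compared to controls" phrasing
implies. The raw scale remains available (`rescale = FALSE`) for
sensitivity analysis. Consequence worth knowing: on the re-standardized
scale a cohort-wide shift of $\delta$ raw units appears as roughly
$\delta\sqrt{m}$ SDs, so even moderate coherent shifts make most tumours
outliers — outlier stratification is informative for *subgroup* effects,
which is how it is used.

## Statistical machinery

**Wilcoxon rank-sum** (tumour vs benign per-sample scores): exact
two-sided p by full enumeration of label assignments when
$n_1+n_2 \le 12$ (tie-safe via pooled mid-ranks; the p-value is the
probability of a rank-sum at least as far from its null mean as
observed), otherwise the normal approximation with tie correction and a
0.5 continuity correction. The exact path is checked against an
independently coded all-relabelings oracle on every small instance in
the suite. The paired signed-rank variant is not offered: the two groups
are different subjects.

**Welch t** on per-sample mean log2 expression of pathway genes; the
zero-variance degenerate case resolves to p = 1 for identical groups and
an explicit error for a noiseless shift (silently returning p = 0 would
hide a data problem). Whether the original analysis summarized per
sample (implemented) or pooled per-gene values is not determinable; the
per-sample summary keeps samples as the unit of inference, matching the
rank test.

**Kaplan–Meier / weighted log-rank**: product-limit estimator with the
events-before-censoring tie convention; the two-group statistic is
$(\sum_j w_j(O_j-E_j))^2 / \sum_j w_j^2 V_j$ over distinct event times
with hypergeometric expectations and variances, $w_j = 1$ (Mantel-Cox)
or $w_j = n_j$ at risk (Gehan–Breslow, early-difference sensitive).
Checked against `survival::survdiff` and against exhaustive permutation
oracles. Cox regression is deliberately out of scope (nothing to
specify); `stratify_by_outlier` also offers median/tertile splits because
"outlier vs rest" versus "high vs low halves" is an open reading —
outlier-vs-rest is the default.

**Small-sample honesty.** At $n \le 8$ subjects the permutation null of
the log-rank statistic is discrete with atoms as large as 0.1, so no
continuous approximation can sit within 0.05 of the naive permutation p
on all instances. The suite compares against the *mid-p* (ties at the
observed statistic count half) and asserts ±0.05 where the test is
decision-relevant (permutation p ≤ 0.15); in the deep-null region the
chi-square approximation is conservative by up to about 0.07 at these
sizes, which the suite pins at a measured 0.1 bound rather than hiding.

**Spearman**: rho is the Pearson correlation of mid-ranks
(tie-corrected by construction); p is exact by permutation enumeration
for n ≤ 8, t-approximated above.

## Clustering determinism

Agglomerative clustering is implemented in-package with Lance–Williams
updates (ward follows the ward.D2 convention) for one reason base R does
not guarantee: a stated tie rule. Among merge candidates at exactly the
minimal distance, the pair whose lexicographically smallest leaf labels
sort first merges first, making dendrograms invariant to input sample
order — asserted as a property test with deliberately duplicated
samples. Heights match `stats::hclust` on tie-free data and an
exhaustive minimum-ΔESS oracle for ward. `pair_adjacency` calls a
matched pair adjacent only when its two members merge with each other
before either merges with anything else (mutual nearest leaves), the
strictest reading of "clustered closely together".

## The synthetic world

`simulate_cohort` draws per-gene baselines
$\mathcal{N}(\mu_0 = 7, \sigma_0 = 1.5)$ (log2-array-like) with i.i.d.
sample noise of SD 1 — the unit in which effect sizes `delta` are
expressed. Defaults emulate a benign-referenced validation cohort of
112 tumours and 28 benign tissues. Effects add `delta` to every gene of
an affected pathway in the first `fraction` of tumours (the planted,
recoverable subgroup). `simulate_pairs` mixes a mate's noise profile
with fresh noise as $\sqrt{\rho}\,\text{mate} + \sqrt{1-\rho}\,\text{new}$
so the within-pair correlation is $\rho$ in expectation. Survival times
are exponential with hazard 0.02/month (median ≈ 35 months, a realistic
biochemical-recurrence scale) times a hazard ratio for truth-outliers;
censoring is independent uniform with its upper bound solved per subject
so the censoring probability equals the configured rate (default 30%).
A counts mode pushes the same signal through a Poisson layer to exercise
the size-factor path.

What the generator does **not** emulate: gene–gene correlation beyond
pathway blocks and pairs, probe effects, batch structure, heavy-tailed
noise, or genes shared between pathways. A green test therefore
establishes that the machinery recovers what it assumes — planted
location shifts under independent Gaussian noise — not that the
biological findings replicate; those require the original
controlled-access cohorts and exact gene lists, which is also why the
acceptance battery is property-based rather than value-matching.

## Numerical and design choices

* SD uses the $n-1$ denominator throughout: reference sets of 11–28
  samples are the norm here.
* Genes with zero reference SD are dropped (with a logged list), never
  turned into NaN; missing values are an error, not an imputation.
* Duplicate gene rows collapse to the highest-mean row (the usual
  multi-probe convention); symbols match case-insensitively after
  trimming.
* Quantile normalization gives tied values the mean of the row-mean
  values their sorted span covers; verified against
  `limma::normalizeQuantiles`.
* Size factors are raw medians of count/geometric-mean ratios
  (`DESeq2::estimateSizeFactorsForMatrix`-equivalent, verified); the
  unit-geometric-mean convention is a flag. The two conventions differ
  by a global constant, so z-scores are unaffected — exactly true at
  pseudocount 0 and asserted as a test; note a nonzero pseudocount
  breaks this exact invariance.
* Exact-test boundaries are inclusive on the evidence side
  (`p = P(|W-E| \ge |w-E|)`), outlier boundaries strictly exclusive, and
  the 6-gene floor inclusive (a 6-gene set is tested; a 5-gene set is
  not).
* A catalog gene may belong to several pathways (succinate
  dehydrogenase legitimately sits in both the TCA cycle and oxidative
  phosphorylation complex II); no exclusivity is enforced.

## Known limitations

* The shipped 23-pathway GMT is a *reconstruction* for demonstration and
  testing; analyses of real cohorts should supply their own curated
  lists.
* The normal-approximation rank test is slightly conservative at very
  small group sizes (measured type-I ≈ 0.039 at 10 + 10) and accurate at
  cohort scale (≈ 0.055 at 112 + 28, inside the 2000-replicate binomial
  CI).
* Benign-referenced scores of benign samples are mildly shrunken (each
  benign sample contributes to its own reference moments); at the
  default cohort sizes the effect is negligible but it is visible in
  type-I rates as mild anti-conservatism.
* `heterogeneity_summary` ranks by SD, which conflates subgroup
  structure with uniform spread; inspect the dendrogram before
  interpreting.
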