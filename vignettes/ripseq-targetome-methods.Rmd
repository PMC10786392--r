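---
title: "Methods: AGO2-RIP-Seq targetome calling and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AGO2-RIP-Seq targetome calling and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscope)
```

This vignette documents the statistical model behind `ripscope`, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The experimental design and its statistical model

An AGO2-RIP-Seq experiment sequences three fractions — Input (total
lysate), AGO2-IP, and an IgG isotype-control IP — under two treatments
(miRNA mimic vs scrambled control), each with biological replicates
(three by default, matching common practice). The analysis starts from a
gene × sample count matrix; alignment and counting are upstream of this
package.

Counts for gene *i* in sample *j* are modelled as negative binomial with
mean $s_j \mu_{ig}$ and dispersion $\alpha_i$ (variance
$\mu + \alpha\mu^2$), where $s_j$ is a sample-specific size factor and
$\mu_{ig}$ the expected normalized abundance in design cell $g$.

**Size factors** are median-of-ratios: over genes expressed in every
sample, the median of $k_{ij} / (\prod_j k_{ij})^{1/m}$, rescaled to
geometric mean 1. If no gene is ubiquitously expressed (a pathological
matrix), total-count scaling is used with a warning.

**Dispersion** is estimated by method of moments on normalized counts,
$\hat\alpha_i = (v_i - m_i \overline{1/s})/m_i^2$, with variances pooled
within treatment groups so real between-group effects do not inflate the
estimate. With only three replicates per group the per-gene estimates have
about four degrees of freedom and are far too noisy to plug into a Wald
test, so the default estimator replaces them with a mean–dispersion trend
fitted by binned averaging of the raw (unfloored) per-gene values — the
same moderation idea used by the established RNA-seq testing frameworks.
Bin means rather than medians are used because the raw moment estimates
are unbiased but strongly right-skewed at few replicates; a median would
be biased low. Raw per-gene and single pooled estimators remain available
(`estimate_dispersion(method =)`). All estimates are floored at `1e-8`;
zero-mean and zero-variance genes are floored and flagged.

**The Wald contrast.** For a two-group contrast (mimic vs scramble within
one fraction) with group means $\hat\mu_a, \hat\mu_b$ of normalized
counts,

$$\mathrm{log2FC} = \log_2\frac{\hat\mu_a + c}{\hat\mu_b + c},\qquad
\mathrm{Var}(\hat\mu_g) = \frac{\hat\mu_g\,\overline{1/s_g} +
\alpha\hat\mu_g^2}{n_g},$$

with the standard error of the log2 fold change by the delta method and a
two-sided p-value from the normal reference. Choices made here:

* **Pseudocount** $c = 0.5$ normalized counts, for fold-change stability
  near zero. It also appears in the delta-method denominator, which makes
  low-count genes conservative rather than explosive.
* **Expression filter:** genes with mean normalized count below 1 across
  the contrast are marked *untested* and given $p = 1$ — kept in the
  table, never silently dropped. Genes with all-zero counts in both groups
  get log2FC 0, $p = 1$.
* **No multiple-testing correction by default.** The filtering rule this
  pipeline implements operates on raw $p < 0.05$ per contrast; the
  three-way intersection is itself the false-positive control. A
  Benjamini–Hochberg column (`padj`) is emitted for users who want it, but
  the target calls do not use it.
* **Group-specific means in the variance.** Using each group's own mean in
  the variance makes the test slightly conservative at low counts (a
  randomly low mean inflates its own Poisson term), which we prefer to the
  alternative bias.

Under the null simulation used in the tests (no planted effects,
dispersion 0.1, 3 vs 3, 2000 genes, ten seeds) the observed fraction of
genes at $p<0.05$ is close to nominal (the acceptance script recomputes
it as `de_null_fpr`); antisymmetry under group swap and invariance to
library-size rescaling are exact properties checked in the suite.

**PCA replicate screen.** Quality control mirrors the common practice of
excluding a replicate that separates from its group in a PCA of
$\log_2(\text{normalized count}+1)$ over the 500 most variable genes. A
sample is flagged when its PC1–PC2 distance to its (fraction, treatment)
centroid reaches 3× the median within-group distance. The comparison is
"at least" with a small relative tolerance, because the canonical
degenerate case — $k$ coincident replicates plus one outlier — lands
*exactly* on the 3× boundary; groups with zero spread are never flagged.
Flagged samples are only excluded when the caller opts in
(`pca_exclude = TRUE`); the exclusion is recorded in the run's provenance
rather than hard-coded.

## Target calling

With `up(X)` = {tested, $p < 0.05$, log2FC > 0} in contrast X and
`down(Input)` the mirror set:

* `ago2_specific = up(AGO2-IP) \ (up(IgG-IP) ∪ up(Input))` — removing
  bead binders (up in both IPs) and indirect transcriptome responders
  (up in Input and proportionally in the IPs);
* `direct_targets = ago2_specific ∩ down(Input)`.

"Specific to the AGO2-IP comparison" is interpreted as exclusion by the
significant **up** sets of the other two contrasts, which is what a Venn
intersection of up-regulated DEG lists computes. A stricter reading —
excluding genes significant in the IgG contrast in *either* direction —
is available as `strict_igg = TRUE`. The signed thresholds are exactly
log2FC > 0 / < 0 with no magnitude cutoff, and raw p-values, as the
filtering rule prescribes. Per-gene provenance records which exclusion
applied.

Relaxing `p_max` can only grow the `up`/`down` sets (tested as a property)
but the direct-target set need not grow monotonically, since both of its
constituent filters move.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated by
recovery of a known truth; its defaults define the validation conditions
and are deliberately fixed:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | gene universe |
| `n_replicates` | 3 | biological replicates per design cell |
| `frac_direct_target` | 0.025 | planted direct targets (50 genes) |
| `frac_bead_binder` | 0.025 | nonspecific bead binders |
| `frac_secondary` | 0.05 | indirect transcriptome responders |
| `ip_enrichment_fold` | 3 | AGO2-IP effect on targets under the mimic |
| `input_depletion_fold` | 0.6 | Input effect on targets under the mimic |
| `bead_fold` | 3 | both-IP effect on bead binders |
| `secondary_fold_log2_sd` | 0.5 | spread of indirect log2 effects |
| `baseline_log_mean/sd` | 5 / 1.5 | log-normal abundance (median ≈ 150) |
| `dispersion` | 0.02 | NB dispersion α |
| `library_size_range` | 0.7–1.3 | per-sample depth multipliers |

Bead binders are *up in both IP fractions* under the mimic, which is
precisely what makes the IgG contrast remove them. Secondary responders
get a per-gene two-sided log2 effect in the Input applied proportionally
in both IPs — a transcriptome change carried passively into every
fraction — which is what makes the Input contrast remove their up-going
half. The default dispersion of 0.02 reflects biological replicates of a
clonal cell line, where typical per-gene dispersions sit in the 0.01–0.05
range; depth multipliers play the role that an external spike-in plays in
the wet protocol.

**What the simulator does not emulate:** read-level artefacts (GC and
fragment bias, multimapping), isoforms, correlated gene–gene expression,
mean-dependent dispersion, and the several-hundred-fold overexpression of
the mimic itself (a miRNA-abundance phenomenon; only its mRNA
consequences are modelled). Passing recovery tests therefore demonstrates
the pipeline's statistical logic, not robustness to upstream artefacts.

**Power and the depletion arm.** The Input-depletion signature is
intrinsically weak: the best possible z-statistic for a 0.6× change at
3 vs 3 replicates is about $\log(0.6)\big/\sqrt{2(\alpha + 1/\mu)/3}$.
At α = 0.02 and moderate abundance this is ≈ −4, giving high power, and
default-condition recovery reaches sensitivity ≥ 0.8 at FDR ≤ 0.2
(recomputed by the acceptance script as `recovery_sensitivity` /
`recovery_fdr`). At α = 0.2 the same bound is ≈ −1.4 — under 30% power at
p < 0.05 for *any* test — so joint sensitivity collapses to roughly 0.2
regardless of method. The test suite includes a recovery run at α = 0.2
documenting exactly this degradation; it is a property of the
information content of three noisy replicates, not of the estimator.

UTR simulation plants one canonical site (7mer-A1, 7mer-m8 or 8mer,
flank-controlled so the planted class is exact) in each direct target's
region and rejection-samples all other regions to contain no occurrence
of the 6mer core, hence no site of any class.

## Seed-match scanning

Site patterns derive from miRNA positions 2–8 by reverse complement:
6mer = rc(m2–m7), 7mer-m8 = rc(m2–m8), 7mer-A1 = 6mer + A,
8mer = 7mer-m8 + A. The scanner reports **every start position** matching
at least one pattern exactly once, labelled with the highest class
matching at that start (8mer > 7mer-m8 > 7mer-A1 > 6mer); overlapping
matches at distinct starts are distinct sites. Note that an 8mer at
position *s* implies a 7mer-A1 at *s*+1, which is reported as its own
start — consumers interested in "sites" rather than "starts" should use
the per-gene class counts from `annotate_targets()`, whose `best_class`
is unaffected. DNA and RNA spellings are transliterated before matching;
ambiguous bases never match; coordinates are 1-based inclusive. No
context/thermodynamic scoring is attempted, and mature sequences are
user-supplied rather than shipped, to avoid freezing an external database
version into the package.

## qPCR calculus

Replicate Ct values above 35 cycles are excluded before averaging
(arithmetically — the aggregation the instrument software performs);
ΔCt = mean Ct(target) − mean Ct(reference) within a sample,
relative expression $2^{-\Delta Ct}$, fold change
$2^{-\Delta\Delta Ct}$. When every replicate of an assay is excluded the
result is *undetermined* — flagged and propagated, never imputed as zero,
because a Ct beyond 35 bounds expression from above but does not measure
it. Table-level quantification pairs each target assay with the reference
assay of the same sample (per-sample pairing, matching paired
tumour/normal designs).

## Survival statistics

Implemented from first principles, with the `survival` package used only
as a cross-check oracle in the test suite:

* **Median split:** low = below the cohort median, high = at or above it.
  Ties at the median go to "high"; a split that empties a group errors.
* **Kaplan–Meier:** product-limit estimate with Greenwood variance and
  log-log 95% bands; median survival is the smallest event time with
  $S(t) \le 0.5$ (undefined if never reached), with a
  Brookmeyer–Crowley-style interval read off the band crossings.
* **Log-rank:** hypergeometric observed-minus-expected sums with the full
  covariance matrix, χ² on k−1 degrees of freedom (generalized inverse if
  a risk set degenerates).
* **Cox regression:** Newton–Raphson on the partial likelihood, Efron tie
  correction by default (more accurate than Breslow at the tie densities
  of monthly follow-up data; Breslow available for compatibility with
  SPSS-style defaults). Covariates are centred for conditioning; the
  gradient convergence criterion is scaled by the log-likelihood
  magnitude; a converged coefficient beyond |β| > 15 is reported as
  monotone-likelihood separation rather than returned. Standard errors
  come from the observed information. The score test at β = 0 with
  Breslow weighting reproduces the log-rank statistic — checked as a
  classical identity in the suite.
* **Backward elimination:** iteratively removes the covariate with the
  largest Wald p above `alpha_out` (default 0.05) and refits; the whole
  fit path is returned. Categorical covariates (stage, smoking) are
  expected pre-encoded by the user; no automatic dummy coding beyond
  numeric/binary columns.

The cohort simulator draws exponential event times with hazard
$\lambda_0\exp(\beta_g\,\text{group} + \sum_k \beta_k x_k)$ and
independent exponential censoring whose rate is calibrated so the
expected censored fraction equals `censoring_rate`
($c = \bar\lambda\, r/(1-r)$); `censoring_rate = 1` censors every record
at a uniform fraction of its event time. The default baseline hazard of
0.02/month gives median event times around 35 months, the scale of a
multi-year oncology follow-up.

## Validation problem sizes

The test suite validates at these scales, chosen to exercise each
property while keeping a full run around half a minute: DE calibration at
2000 genes × 10 seeds; default-condition recovery over 8–20 simulated
studies; log-rank type-I error over 1000 null cohorts of n = 200; Cox
hazard-ratio recovery over 100 cohorts of n = 500; seed-scanner
equivalence against a brute-force oracle on 10 kb random sequences. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
numbers at comparable sizes from a single command-line seed.

## Known limitations

* The negative-binomial test has no GLM layer: only two-group contrasts,
  no covariates or batch terms, and no shrunken fold-change estimator.
* Exact reproduction of any particular published gene list from public
  RIP-seq data is out of scope: such lists depend on the (often
  unnamed) upstream DE method, and this package's test is its own.
* The seed scanner deliberately ignores non-canonical (bulged, offset,
  3'-compensatory) sites and conservation/context scores.
* The survival module fits proportional hazards only — no time-varying
  covariates, frailty, or competing-risk estimators; the "cumulative
  incidence" reported is the Kaplan–Meier complement.
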