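---
title: "Methods: translating CMS classification to liver metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translating CMS classification to liver metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The consensus molecular subtypes (CMS1 MSI/immune, CMS2 canonical, CMS3
metabolic, CMS4 mesenchymal/stromal) are a transcriptomic taxonomy of
primary colorectal cancer. A bulk expression profile of a liver
metastasis, however, is a mixture: cancer cell signal plus a variable
amount of surrounding hepatocyte tissue. A classifier trained on primary
tumors sees query data whose distribution differs from its training
distribution, and the hepatocyte program — a strongly metabolic
expression phenotype — systematically distorts calls. `metacms`
implements the metastasis-translated pipeline: quantify the liver
background per sample, regress it out, classify on cancer-cell-intrinsic
features, and quantify intra-patient subtype heterogeneity.

## The background model and its assumptions

The liver background of sample $i$ is summarized by a single scalar.
With $z$ the gene-wise mean-centered log2 matrix and $g_j \in \{0,1\}$
indicating hepatocyte-marker membership,

$$p_i = \sum_j z_{ij} g_j, \qquad
  P_i = \frac{p_i - p_{\min}}{p_{\max} - p_{\min}}.$$

Assumptions worth making explicit:

* **One axis.** A single scalar per sample, not a full cell-type
  deconvolution. Adequate when hepatocytes are the dominant non-tumor
  signal, which is the working assumption for liver metastases.
* **Cohort-relative scale.** $P$ is min–max normalized within the
  cohort: $P_i = 1$ means "most contaminated sample here", not "pure
  liver". The QC filter therefore works on the *raw* scores $p_i$,
  compared against scores of pure normal-liver references (threshold:
  their 10th percentile, linear interpolation). We do not min–max the
  reference jointly with tumors; the alternative would make the
  threshold depend on the tumor cohort's range.
* **Degeneracy.** If all $p_i$ coincide the normalization is undefined;
  the estimate carries a `degenerate` flag, $P \equiv 0$, and the
  regression refuses to run rather than divide by zero.

The adjustment fits, per gene, ordinary least squares of expression on
$P$ **with intercept** — stated explicitly because residuals differ
without one — and replaces values by residuals. A single global scalar
then shifts the whole matrix so its minimum is exactly 0. We shift by
$\max(0, -\min)$ rather than the unconditional $|\min|$: on an
(improbable) all-positive residual matrix the latter would inflate every
value instead of anchoring the minimum at zero. `literal_shift = TRUE`
restores the unconditional behaviour for compatibility.

## Feature selection

Run on microenvironment-free reference profiles (cell lines, organoids),
two sequential filters:

1. maximum expression strictly above the first tertile of the **pooled**
   value distribution of the whole matrix — "of the data set" is read as
   pooled, not per-gene, since the intent is dropping never-expressed
   genes;
2. 10th–90th inter-percentile range (IPR) at or above the 90th
   percentile of the gene-wise IPR distribution *computed after filter
   (1)*, ties kept.

Whether the two filters are independent or sequential is genuinely open;
we fix sequential (the IPR reference population is then "expressed
genes", which is the more interpretable choice). All percentiles
package-wide use linear interpolation between order statistics
(quantile type 7).

## The classifier

Nearest shrunken centroids in its canonical form. Per gene $j$ and class
$k$: pooled within-class standard deviation $s_j$ (denominator $n-K$),
stabilizer $s_0 = \operatorname{median}_j s_j$,
$m_k = \sqrt{1/n_k - 1/n}$, standardized deviation
$d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))$, soft-thresholded
at $t$, and shrunken centroid
$\bar x'_{kj} = \bar x_j + m_k (s_j + s_0)\, d'_{kj}$. Prediction uses

$$\delta_k(s) = \sum_j \frac{(x_{js} - \bar x'_{kj})^2}{(s_j + s_0)^2}
  - 2 \log \pi_k, \qquad
  \text{posterior}_k \propto e^{-\delta_k/2},$$

with the call withheld (NA) when the maximum posterior is below the
cutoff $c$ (default 0.5, the conventional operating point; the `nearest`
label is always reported). `cutoff_for_na_fraction()` solves $c$ for a
target unassigned fraction on a given cohort, the operational rule of
matching a reference classifier's NA rate.

Numerical choices: shrinkage is applied directly in expression units
(`|diff| − t·m_k(s_j+s_0)` clipped at 0), which avoids `Inf · 0` for
zero-dispersion genes; posteriors subtract the row maximum of
$-\delta/2$ before exponentiating, making them exactly invariant to a
constant added to all $\delta_k$; at $t = \infty$ centroids collapse
onto the overall centroid and posteriors equal the priors exactly.

**Tuning.** Leave-one-out cross-validation over a grid of $t$ (default
30 linear points from 0 to the largest $|d_{kj}|$). During tuning the
confidence gate is disabled — accuracy would otherwise depend on $c$ —
and ties are broken toward the largest $t$ (sparsest model). The default
operating point is $t = 1.5$.

**Distillation.** A random forest trained on the NSC's confident labels
against *raw* (unadjusted) expression over the same features absorbs the
background axis into its splits, so the deployed model needs no marker
panel or normal-liver reference. No random-forest package is assumed in
the target environment, so the forest is implemented in-package: bagged
CART trees, Gini impurity, $\sqrt{p}$ features per split, grown to
purity, posterior = vote fractions, deterministic given a seed. Default
500 trees; tests use fewer for speed, which only loosens the vote
granularity.

## Projection and heterogeneity

PCA is fitted on primary tumors only (top-5000-variance genes, centered,
unscaled — `prcomp` defaults, and subtype structure lives in
location/scale that unit-variance scaling would distort), and metastases
are projected by subtracting *training* means and applying the training
loadings. Singular-vector signs are arbitrary, so each loading is
oriented to make its largest-magnitude entry positive; score tables are
then reproducible. Variance explained is relative to the retained genes,
which is how such percentages are conventionally displayed.

Heterogeneity is determined lesion-wise: multiple samples of one lesion
collapse by majority label, ties → NA; a patient is heterogeneous when
at least two *confidently* classified lesions disagree. Transcriptomic
spread is the maximum pairwise Euclidean distance over the patient's
samples in raw PC1–PC3 scores (no standardization — distances follow
the stated dimensionality-reduction-then-Euclidean procedure). The
worst-subtype rule (any CMS1/CMS3 → `CMS1/3`; else any CMS4 → `CMS4`;
else `CMS2`) is monotone: adding a better-prognosis lesion never
upgrades a patient. For survival stratification, lesions contribute
their nearest label, so every patient is stratified; the export caps
follow-up at 60 months with the event cleared at the cap.

## Gene-set scores

The single-sample score is a normalized mean-rank statistic: with genes
ranked within each sample (average ranks on ties) and $G$ genes total,

$$\text{score}(S) = \frac{\overline{\text{rank}}(S) - (G+1)/2}{G/2}
  \in [-1, 1].$$

This deliberately replaces kernel-density GSVA. The scores are used only
comparatively (correlations with components, between-group shifts), and
the rank statistic preserves those contrasts while being exactly
testable: the all-genes set scores 0, a singleton top gene scores
$(G-1)/G$, scores are invariant under any strictly monotone per-sample
transform and anti-symmetric under rank reversal.

## Odds ratios

Two estimators are provided: the sample cross-product OR with Woolf
log-normal CI (Haldane–Anscombe 0.5 on zero cells, with a warning), and
the conditional maximum-likelihood estimate with exact CI as computed by
`stats::fisher.test` — the default, since contingency statements of this
kind conventionally come from Fisher's exact machinery. The cMLE shrinks
toward 1 relative to the sample OR, which the tests verify on a table
battery.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to
tests. 2000 genes: four 50-gene subtype blocks (CMS1 MSI/immune, CMS2
canonical, CMS3 metabolic, CMS4 mesenchymal/EMT), a 50-gene hepatocyte
block, the rest background. Flat log2 baseline 7 (hepatocyte genes 4 in
tumor cells), block effect +2, noise sd 1 — array-like log2 magnitudes.
240 primaries (60 per class); 120 metastases with class weights
(0.05, 0.40, 0.05, 0.50), echoing the near-90% CMS2/CMS4 predominance in
resected liver metastases; patients carry 1–4 lesions, deviating from
the patient's base subtype with probability 0.25; 10 pure normal-liver
references. The liver profile expresses the hepatocyte block at 12 and
the metabolic block at +4 — hepatocytes are metabolic tissue, and this
is precisely what makes unadjusted classification collapse toward CMS3
and gives the regression its purpose. Metastasis sample $s$ is
$(1-w_s)\cdot\text{tumor} + w_s\cdot\text{liver}$ with
$w \sim U(0.2, 0.5)$; mixing is linear in the log2 working domain — a
simplification of convolution in linear space, consistent with the
linearity of both the background score and the regression.

The microenvironment-free reference panel (60 profiles, block effect 3,
noise 0.5) yields 195 selected features under the default geometry —
the four blocks are, by construction, almost exactly the top 10% of
expressed genes by IPR.

What the generator does **not** emulate: platform/batch effects,
probe-level noise, correlated gene-gene structure within blocks,
copy-number-driven expression, partial-volume nonlinearity of real
mixtures. A green pipeline test therefore establishes internal
consistency of the method under its own assumptions, not performance on
real arrays.

One empirical caveat the tests surfaced: applying a raw-scale-trained
NSC to residual-scale adjusted data works because cohort-level location
offsets cancel in centroid *contrasts*, but the cancellation is exact
only in expectation. With very small training cohorts (≈12 per class)
centroid sampling noise is amplified by the offset and accuracy
degrades; at the stated 60 per class the signal dominates by an order of
magnitude. The end-to-end tests therefore run at the default geometry.

## Known limitations

* Gene identifiers are opaque strings; no symbol/ID mapping or
  cross-platform harmonization is attempted.
* The bundled hepatocyte panel is synthetic (it matches the generator);
  real analyses must supply a curated liver-specific marker list.
* The exact published feature list and gene-set memberships depend on
  unpublished reference matrices and are out of scope; the pipeline
  reproduces the *procedure*, not the artifact.
* Survival modeling itself (Cox, Kaplan–Meier) is delegated to standard
  survival tooling; this package only produces the stratified table.
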