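# metacms

Consensus molecular subtype (CMS) classification for colorectal cancer
**liver metastases**.

Bulk expression profiles of liver metastases are a mixture of cancer cell
signal and surrounding hepatocyte tissue. Classifiers trained on primary
tumors therefore misbehave on metastases: the liver background violates
the assumption that query and training data share the same expression
distribution. `metacms` implements a metastasis-translated classification
pipeline:

1. **Liver-background estimation.** For sample *i*, with `z` the gene-wise
   mean-centered log2 expression matrix and `g_j` an indicator for
   membership in a hepatocyte marker panel (e.g. *ALB*, *F9*),

   ```
   p_i = Σ_j z_ij g_j ,   P_i = (p_i − p_min) / (p_max − p_min) ∈ [0, 1]
   ```

   Samples whose raw score reaches the 10th percentile of normal-liver
   reference scores are flagged as liver-dominated and discarded.

2. **Background regression.** Per gene, ordinary least squares of
   expression on `P` (with intercept); residuals replace the data, then a
   single global shift sets the matrix minimum to 0.

3. **Feature selection.** On microenvironment-free reference profiles
   (cell lines / organoids): keep genes whose maximum expression exceeds
   the first tertile of the pooled data, then keep the top 10% by
   10th–90th inter-percentile range — robustly expressed,
   cancer-cell-intrinsic candidates.

4. **Nearest shrunken centroids (PAM).** Class centroids soft-thresholded
   toward the overall centroid by `t` on the standardized scale
   `d_kj = (x̄_kj − x̄_j) / (m_k (s_j + s0))`; discriminant
   `δ_k(s) = Σ_j (x_js − x̄′_kj)² / (s_j + s0)² − 2 log π_k`; posteriors
   `softmax(−δ/2)` gated at a confidence cutoff (default 0.5; `t` tuned
   by leave-one-out cross-validation, default 1.5). An optional
   random-forest distillation learns the NSC labels from *raw* expression
   so that no marker panel or normal-liver reference is needed at
   deployment.

5. **Projection & heterogeneity.** PCA fitted on primary tumors (top-5000
   variance genes), metastases projected onto the same components;
   intra-patient inter-lesion heterogeneity from confident lesion labels;
   maximum pairwise Euclidean distance in PC1–PC3; patient-level
   **worst-subtype stratification**: any CMS1/CMS3 lesion → `CMS1/3`,
   else any CMS4 → `CMS4`, else `CMS2`; survival export with 5-year
   censoring.

A synthetic-cohort generator with full ground truth (subtype blocks, an
MSI-like axis, hepatocyte contamination at controlled mixing weights)
exercises every stage.

## Worked example

```r
library(metacms)

## 1. a synthetic cohort with known subtypes and liver contamination
cfg <- synthetic_config(seed = 1)
cohort <- generate_cohort(cfg)
ann <- cohort$annotation

## 2. cancer-cell-intrinsic features from a microenvironment-free panel
features <- select_intrinsic_features(generate_reference_panel(cfg))
length(features$genes)
#> [1] 195

## 3. train the shrunken-centroids classifier on labeled primaries
prim <- cohort$expr[, ann$sample_id[ann$sample_type == "primary"]]
labels <- with(cohort, truth$true_class[match(colnames(prim), truth$sample_id)])
model <- train_nsc(prim, labels, features, t = 1.5)

## 4. estimate and regress out the liver background in the metastases
mets <- cohort$expr[, ann$sample_id[ann$sample_type == "metastasis"]]
est <- estimate_background(mets, cohort$markers)
adjusted <- regress_out_background(mets, est)

## 5. classify
calls <- predict_nsc(model, adjusted)
head(calls, 3)
#>   sample_id         CMS1         CMS2         CMS3         CMS4 nearest call
#> 1      M001 9.999759e-01 2.980360e-06 2.015802e-05 9.399846e-07    CMS1 CMS1
#> 2      M002 1.691065e-12 1.000000e+00 2.428849e-11 5.104363e-14    CMS2 CMS2
#> 3      M003 1.000000e+00 4.126192e-12 1.926307e-11 1.324816e-13    CMS1 CMS1
truth_met <- with(cohort, truth$true_class[match(calls$sample_id, truth$sample_id)])
mean(calls$nearest == truth_met)
#> [1] 1
```

Every metastasis is recovered despite 20–50% hepatocyte admixture; the
same classifier applied to the *unadjusted* matrix at 50% admixture drops
to ~0.14 accuracy (the liver profile resembles the metabolic subtype and
swallows everything).

Subtype enrichment in metastases versus primaries (confident calls only;
OR > 1 = enriched among metastases):

```r
prim_calls <- predict_nsc(model, prim)
proportion_shift(calls$call, prim_calls$call)
#>   class n_met n_prim        or  conf_low conf_high
#> 1  CMS1    27     60 0.8713124 0.4969159 1.5011447
#> 2  CMS2    29     60 0.9561561 0.5515371 1.6334746
#> 3  CMS3    17     60 0.4960478 0.2570821 0.9167892
#> 4  CMS4    47     60 1.9278158 1.1735455 3.1652903
```

Intra-patient heterogeneity and worst-subtype strata:

```r
pca <- fit_pca(prim, n_genes = 2000)
tab <- build_patient_lesion_table(calls, ann[ann$sample_type == "metastasis", ],
                                  project_pca(pca, adjusted))
het <- assess_heterogeneity(tab)
mean(het$heterogeneous[het$n_confident_lesions >= 2])
#> [1] 0.6944444
table(worst_subtype_stratify(tab)$stratum)
#> CMS1/3   CMS2   CMS4
#>     25      6     17
```

## Command line

`inst/cli/metacms` (an Rscript launcher around `metacms_cli()`) exposes
the pipeline as subcommands:

```sh
metacms simulate --seed 42 --outdir sim/
metacms features --ref cellines.tsv --out features.txt
metacms background --expr mets.tsv --markers liver.txt --out P.tsv \
        --adjust --adjusted-out mets_adj.tsv
metacms train --expr primaries.tsv --labels labels.tsv \
        --features features.txt --t 1.5 --out model.json
metacms classify --model model.json --expr mets.tsv \
        --adjust-background --markers liver.txt --out calls.tsv
metacms pca | project | gss | het | stratify | or ...
```

Outputs are write-once (`--force` to overwrite) and every output gets a
JSON provenance sidecar. Stochastic commands require `--seed`.

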