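# qihc — unbiased quantitative immunohistochemistry and colocalization

`qihc` is an R package for researchers who quantify protein expression in
tissue-microarray (TMA) cores and want numbers instead of eyeball scores. It
implements the full analysis chain around DAB (3,3'-diaminobenzidine)
brightfield staining:

* **Per-core quantification** — grayscale conversion, stain thresholding
  (Otsu or fixed cut), connected-component "particle" analysis (count, total
  area TA, average size, area fraction AF = 100·TA/total pixels), and
  tissue-amount standardization via the inverted image
  (`normalized_signal = TA / tissue_area`).
* **Cohort statistics** — Mann–Whitney U (exact enumeration or tie-corrected
  normal approximation), Kolmogorov–Smirnov normality screening, fold change
  of group means, and mountain-plot AUC on a shared binning.
* **Biomarker diagnostics** — probit transform Φ⁻¹(AF/100), empirical ROC
  with sensitivity/1-specificity and likelihood ratios
  (LR+ = sens/(1−spec)) at every criterion, binormal ROC from per-class
  moments (AUC = Φ(a/√(1+b²))), and two-marker logistic regression
  (logit p = β₀+β₁x₁+β₂x₂) with the in-sample percent of cases correctly
  identified.
* **Colocalization** — maximum-intensity z-projection, background-excluding
  pixel masks, pixel-wise Pearson coefficient per channel pair, and paired
  comparison of matched relapse vs non-relapse cores.
* **Synthetic ground truth** — generators for DAB cores (known tissue and
  stain masks), fluorescence stacks with prescribed channel correlations,
  and cohorts with prescribed group moments, so every stage is testable
  without patient data.

Pipelines (`run_dab_pipeline()`, `run_coloc_pipeline()`) are blind by
design: quantification never sees diagnosis or outcome labels, outputs are
frozen-column CSVs, and every run writes a manifest with the serialized
configuration, its MD5 hash and the seed. Re-running a pipeline with the
same configuration and seed is byte-identical.

## Worked example

```r
library(qihc)

# a synthetic core with 4% true stained area on 60% tissue
core <- generate_core_image(core_spec(256, 256, tissue_fraction = 0.6,
                                      stained_fraction = 0.04,
                                      blob_count = 20, seed = 7))
quantify_core(core, quant_config(dab_threshold = list(method = "fixed",
                                                      lo = 0, hi = 120)))
#>           core_id count total_area average_size area_fraction tissue_area
#> 1 synthetic_seed7    20       2622        131.1      4.000854       39324
#>   normalized_signal
#> 1        0.06667684
```

The measured area fraction (4.0009%) equals the generator's ground truth
exactly on a noiseless core, and `normalized_signal` is the stained/tissue
pixel ratio (0.04/0.60 = 0.0667).

```r
# a cohort at published TMA moments: benign 1.66 +/- 0.12 (SE), malignant 4.09 +/- 0.27
tab <- generate_cohort(cohort_spec(seed = 42), marker_name = "BTF3")
cohort_group_stats(tab)
#>  marker n_benign mean_benign se_benign n_malignant mean_malignant
#>    BTF3      236        1.49     0.107         228              4
#>  se_malignant fold fold_auc     U        p
#>         0.261  2.7      2.6 13989 3.76e-19

roc <- empirical_roc(probit_transform(tab$area_fraction),
                     as.integer(tab$diagnosis == "malignant"))
roc
#> <roc_result> 465 operating points, n0 = 236, n1 = 228
#>   empirical AUC = 0.7400
```

The fold change (~2.5 implied by the group means), the Mann–Whitney p well
below 10⁻⁴ and an AUC in the low 0.7s are the behavior expected of a marker
whose malignant expression is 2–3 fold above benign with heavy overlap —
adequate for diagnosis singly, better in a two-marker logistic panel
(`fit_logistic_pair`).

```r
st <- generate_fluorescence_stack(fluor_spec(pairwise_rho = 0.73,
                                             n_pixels_per_slice = 1e4, seed = 3))
pearson_coloc(st$channels[[1]][, , 1], st$channels[[2]][, , 1],
              channel_pair = "BTF3_FITC~HINT1_Cy3")
#> <coloc_result> BTF3_FITC~HINT1_Cy3: r = 0.7262 over 10000 px [all_pixels]
```

A command-line wrapper for the pipelines ships at `inst/cli/qihc.R`
(subcommands `quantify`, `coloc`, `simulate-cores`).

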