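---
title: "Methods: unbiased DAB quantification, biomarker diagnostics and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbiased DAB quantification, biomarker diagnostics and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qihc)
```

## The measurement problem

Immunohistochemistry scoring by eye is subjective and poorly reproducible.
`qihc` implements an automated alternative for tissue-microarray (TMA) cores
stained with the brown DAB chromogen: convert the RGB core image to
grayscale, threshold the dark stain, measure the stained "particles"
(connected components), and express the signal as an **area fraction**
(AF = 100 · stained pixels / image pixels). Because cores differ in how much
tissue they carry, the signal is also **standardized to the amount of
tissue**: the grayscale image is inverted so tissue becomes bright, tissue is
segmented by the same threshold-and-particle machinery, and the
tissue-normalized signal is `total_area / tissue_area`. Both quantities are
reported per core, because published AF tables are ambiguous about which one
they print.

Downstream, per-core values feed three analyses:

1. **Cohort comparison** — benign vs malignant cores by Mann–Whitney U
   (rank-based; AF distributions are right-skewed), fold change of group
   means, and mountain-plot AUC as a confirmatory integral measure.
2. **Diagnostics** — probit transform of AF, empirical and binormal ROC
   curves with sensitivity/1-specificity and likelihood ratios per criterion,
   and two-marker logistic regression with the in-sample percent of cases
   correctly identified.
3. **Colocalization** — pixel-wise Pearson correlation of fluorescence
   channel pairs on max-projected stacks, compared between matched relapse
   and non-relapse cores with a paired t-test.

## The quantification chain and its tunables

`quantify_core()` runs: `rgb_to_gray` → stain threshold → `label_particles`
→ `filter_particles` → particle statistics → inverted-image tissue
segmentation → tissue normalization.

* **Grayscale conversion** (`gray_mode`): default is the unweighted channel
  mean `round((R+G+B)/3)`, the convention of the common particle-analysis
  tools; Rec. 601 luma is available for sensitivity analysis. 8-bit input is
  promoted to 16-bit (×257), mirroring the usual "convert to 16-bit" macro
  step.
* **Stain threshold** (`dab_threshold`): the original protocol used fixed
  cuts chosen manually per antibody, but those values were never published.
  The package default is therefore Otsu's cut with the dark side kept
  (`otsu_dark`); any manual choice can be reproduced exactly with
  `list(method = "fixed", lo =, hi =)` in 8-bit gray levels. **Limitation:**
  Otsu assumes a two-class histogram. A brightfield core image has three
  classes (white background, mid-gray tissue, dark stain), and when the
  background dominates, the single Otsu valley falls between background and
  tissue rather than between tissue and stain. For quantitative validation
  work on synthetic cores we therefore use a fixed cut placed between the
  known stain and tissue gray levels (0–120 of 255), which plays the role of
  the protocol's manually chosen threshold. On real material a per-antibody
  fixed cut chosen on a few random cores — exactly as the original protocol
  did — is the recommended setting.
* **Tissue segmentation** (`tissue_margin`, default 10 gray levels): on the
  inverted image, tissue is bright. The Otsu cut for tissue is computed with
  the already-detected stain pixels excluded (otherwise heavy stain makes
  this histogram trimodal too), the margin is added to keep faint vignette
  out, and the stain mask is rejoined, since stained pixels are tissue.
* **Connectivity** (8 by default, the Analyze-Particles convention) and the
  particle filters (`size_min = 0.5` px², circularity 0–1) are configurable;
  the default filter bounds are deliberately pass-all, matching the printed
  protocol settings, and are retained for fidelity.
* **Perimeter and circularity**: the perimeter is the crack length — the
  number of exposed pixel edges — and circularity is
  `min(1, 4π·area/perimeter²)`. This convention is exactly testable (single
  pixel: 4 and 0.785; 3×3 square: 12 and 0.785) but orientation-biased: a
  large digital disc has crack perimeter ≈ 8r, so its circularity tends to
  π²/16 ≈ 0.617, not 1. Since the protocol's circularity filter is pass-all,
  this bias affects no reported quantity.

## What the synthetic generator emulates — and what it does not

`generate_core_image()` produces a circular tissue region (RGB ≈ 200,170,180)
on a near-white slide (≥ 245) with dark-brown elliptical stain blobs
(≈ 90,60,30), unioned, confined to tissue, and sized by bisection so the true
stained fraction matches the request to well under half a percentage point.
The three classes are separated by > 40 unweighted gray levels, so
thresholding is well-posed. Ground-truth masks ride along with the image.
Default geometry is 1024×1024 px (the acquisition size was never published;
tests use 96–256 px cores, which is sufficient because area fraction is
scale-free — one of the tested invariants).

`generate_fluorescence_stack()` mixes latent standard-normal fields through
the symmetric square root of the target correlation matrix, then maps each
channel affinely to the 16-bit range (mean 32768, SD 6553; clipping is
negligible at these settings). The target Pearson correlation holds in
expectation; the realized per-stack correlation is returned as ground truth
and is within ±0.05 of target at 10⁴ pixels (mean absolute error ≤ 0.02 at
10⁵ pixels over 20 seeds, a tested invariant). The eigendecomposition route
(rather than Cholesky) handles singular targets such as ρ = 1 exactly.

`generate_cohort()` draws per-core area fractions from a gamma (default) or
lognormal family — both strictly positive and right-skewed, as stain
fractions are — at group means and standard errors taken from published TMA
cohort tables (defaults: benign 1.66 ± 0.12 SE at n = 236, malignant
4.09 ± 0.27 SE at n = 228; per-core SD is `se·√n`). Matched-pair
colocalization cohorts are drawn with *independent* arms: no within-pair
correlation is published, and we decline to invent one (see "Known
limitations").

None of the generators attempt photorealism: no gland morphology, no
stain-unmixing physics, no point-spread blur, no JPEG artifacts (all output
is lossless PNG/TIFF; a JPEG-quality field exists in the spec of a core for
compatibility but is not encoded). Passing tests therefore demonstrate that
the *measurement and statistics machinery* is correct on images whose truth
is known — not that the thresholds generalize to arbitrary real slides,
where staining chemistry, illumination and epithelial architecture vary.

## Numerical and statistical choices

* **Mann–Whitney U** is computed from midrank sums. The exact method
  enumerates all group relabelings (practical to n₁+n₂ = 16) and uses the
  symmetric two-sided tail |U − n₁n₂/2|; the default normal approximation is
  tie-corrected with a 0.5 continuity correction and agrees with the exact
  enumeration to < 0.02 at n = 6 + 6 and with `wilcox.test` to 10⁻⁸.
* **Mountain-plot AUC** integrates the per-bin *value mass* (not counts) by
  trapezoid over a zero-padded polyline on a shared Freedman–Diaconis
  binning; with equal group sizes the AUC ratio converges to the ratio of
  group means, which is why it "confirms" the fold change.
* **Probit transform**: AF/100 is clamped to [10⁻⁶, 1−10⁻⁶] (the resolution
  of a megapixel image) before `qnorm`; a rank-based inverse-normal mode is
  provided. Both are strictly monotone, so the empirical ROC is invariant —
  an asserted property.
* **ROC**: "criterion >" orientation (malignant = high scores) with a warning
  when AUC < 0.5; empirical AUC via the Mann–Whitney identity; binormal fit
  from per-class moments (`a = (m₁−m₀)/s₁`, `b = s₀/s₁`,
  `AUC = Φ(a/√(1+b²))`) because a moment fit is deterministic and exactly
  testable, unlike ML on the curve. Both AUCs are always reported, since
  published AUCs rarely say which estimator they are.
* **Two-marker logistic regression**: maximum likelihood via `glm`; on
  detected separation the model is refit with a ridge penalty of λ = 10⁻⁴ on
  the slopes only, keeping estimates finite without materially changing the
  classification rate, and the result is flagged. Percent correctly
  identified is in-sample at cutoff 0.5 — deliberately so, because the
  published panel percentages are in-sample; no cross-validation is claimed.
* **Colocalization**: default pixel mask is `either_above` with per-channel
  Otsu thresholds — including empty background inflates r; an `all_pixels`
  mode exists for sensitivity analysis, and every result row records its
  mask mode. The group comparison defaults to a paired t-test (cores are
  matched pairs); a Fisher-z option is provided because r is bounded.
* **Determinism**: every generator is a pure function of its spec (the seed
  is saved/restored around generation), and re-running a pipeline with the
  same configuration and seed is byte-identical — both tested.

## Known limitations

* **Epithelium**: analysis is restricted by the tissue mask only; no
  epithelial segmentation is attempted (no training data), so
  "epithelium-specific" claims require the reader to trust the stain's own
  localization.
* **Cores, not patients**: multiple cores per patient are treated as
  independent units, replicating common TMA practice; no clustering
  correction is applied.
* **Paired power at n = 4**: with independent arms at group moments
  0.73 ± 0.02 vs 0.60 ± 0.07 (SD), the two-sided paired t-test at α = 0.05
  has power of roughly two thirds. A single observed significant result at
  n = 4 is therefore entirely plausible, but *reliable* replication at that
  sample size would require within-pair correlation that no published value
  supports; the package reports the test honestly rather than assuming one.
* **Threshold transfer**: Otsu defaults are well-posed on the synthetic
  three-class images and on background-free fields, but real cores with weak
  staining or heavy background need a manually chosen fixed cut, exactly as
  in the original protocol.

## Problem sizes used in the test suite

Unit tests run on 64–256 px synthetic cores, 10⁴–10⁵-pixel fluorescence
fields, and cohorts of 5–2000 cores per group; the end-to-end significance
replication uses 230 cores per group over 100 seeded replicates, and ROC
calibration uses 200 scores per group over 50 replicates. These sizes were
chosen so each check is statistically decisive for the property it tests.
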