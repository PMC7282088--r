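---
title: "Model-based analysis of breast lesions from directional DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of breast lesions from directional DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwicadx)
```

## The problem

Mean apparent diffusion coefficient (ADC) over a hand-drawn region of
interest (ROI) is the standard quantitative discriminator of benign from
malignant breast lesions on diffusion-weighted MRI (DWI). It is degraded by
exactly the things hand-drawn ROIs cannot avoid: cystic or necrotic
subregions with high diffusivity, partial-volume averaging at the lesion
boundary, and reader-to-reader variability in where that boundary is drawn.
`dwicadx` implements a model-based alternative that (i) keeps the three
diffusion-encoding gradient directions separate instead of averaging them,
(ii) replaces the hand ROI with a computer-grown, topologically connected 3D
lesion model, and (iii) analyzes the lesion core and the lesion periphery as
distinct sub-regions with distinct features.

## The model, stage by stage

**Directional ADC maps.** For each direction $d \in \{r, p, s\}$ (readout,
phase, slice) the ADC is computed voxelwise from the $b=0$ signal $S_0$ and
the high-$b$ signal $S_{d,b}$:

$$ADC_d = \frac{1}{b}\,\ln\!\left(\frac{S_0}{S_{d,b}}\right),$$

stored in units of $10^{-3}\,\mathrm{mm^2/s}$ so that typical breast tissue
reads 0.5–3 and the cancer-like cutoff reads 1.37. Voxels with non-positive
signals, or with $S_{d,b} > S_0$ (a negative ADC, i.e. noise), are set to 0
— the most conservative, "fully restricted" value — and counted for QC. The
choice of 0 is ours; the measurement model does not define these voxels.

**Augmented ADC.** The region-growing intensity field is the augmented map
$auADC_d = S_0 \cdot ADC_d$. The multiplication by $S_0$ (a T2-weighted,
distortion-matched image) restores lesion conspicuity that the ADC map
alone lacks, while preserving the diffusion contrast.

**3D lesion model.** Starting from a seed voxel — the maximum $auADC_d$
inside the hand ROI on the index slice (the annotated slice with the
largest ROI; ties toward the lower slice) — the model is the connected
component of $\{auADC_d > t\}$ containing the seed, by default under
26-connectivity (configurable to 6 or 18). The threshold $t$ is selected by
maximizing the Jaccard index between the model's index-slice cross-section
and the hand ROI. Candidate thresholds are the distinct $auADC_d$ values in
the hand ROI's bounding box dilated by 5 px in-plane (all slices), capped
at 512 evenly spaced quantiles when more are present; the model is grown
within that padded box. The scan is implemented as a single union-find
sweep over voxels in descending intensity order, so it is exact over the
candidate set at any volume size. Ties in Jaccard go to the lowest
threshold (the most inclusive model). The model is connected in 3D but its
2D cross-sections may be disconnected — a hallmark of irregular lesions
that pure 2D methods cannot represent.

**Core and periphery.** The lesion-core sub-ROI is the intersection of the
hand ROI with the model's index-slice cross-section; the peri-lesion
sub-ROI is the remainder of the hand ROI. Each direction yields its own
pair, so each reader contributes three core/peri pairs per lesion.

**Features.** Voxels are classified at a fixed cutoff of
$1.37 \times 10^{-3}\,\mathrm{mm^2/s}$: below is cancer-like, at or above
is benign-like. Two lesion features follow:

* **SDAC** — the sample standard deviation (n−1, three directions) of the
  cancer-like area in the core. A directionally anisotropic lesion
  restricts diffusion differently along different gradients, so its
  cancer-like area varies across directions; higher SDAC means higher
  probability of cancer. When the mean cancer-like area is below
  6.67 mm² (a three-direction total below 20 mm²) the cancer-like pixels
  are treated as spurious and SDAC is forced to exactly 0. The rule is
  implemented on the mean; the two printed forms are equivalent.
* **ACMB** — the cancer-like minus benign-like area in the periphery,
  summed over the three directions, negative values permitted. Infiltrative
  margins push ACMB up; benign rims push it down.

Voxel classification uses each direction's own $ADC_d$ map within that
direction's sub-ROIs, mirroring the per-direction construction of the
models. The baseline discriminator is the mean of the direction-averaged
ADC over all of a reader's annotated ROI voxels.

**Classifier and ROC.** SDAC and ACMB are combined by logistic regression
with repeated stratified 5-fold cross-validation (default 20 repeats, a
choice that stabilizes fold noise at cohort sizes near 60): each lesion's
score is its mean out-of-fold predicted probability. ROC curves are
binormal, fitted by Gaussian moment matching on the scores —
$a = (\mu_+-\mu_-)/\sigma_+$, $b = \sigma_-/\sigma_+$,
$AUC = \Phi(a/\sqrt{1+b^2})$ — with the rank-based empirical AUC always
reported alongside, since the binormal and empirical estimates answer
slightly different questions on small cohorts. Sensitivity is read at 90%
specificity, $\Phi(a + b\,\Phi^{-1}(0.10))$. Moment matching was chosen
over latent-scale maximum likelihood because it is deterministic,
transparent, and exact for the Gaussian synthetic scores used in
validation; degenerate scores (a zero within-class SD) fall back to the
empirical curve with a warning.

**Agreement.** Inter-observer variability is measured by the Dice
coefficient (DSC), between the two readers' hand ROIs and between their
algorithm-generated core sub-ROIs (averaged over the three directions),
with DSC > 0.8 flagged as substantial agreement. The paired hand-vs-core
DSCs are compared with the Wilcoxon signed-rank test, the substantial
-agreement indicators with McNemar's test, and benign-vs-malignant ROI
sizes with Welch's two-sided t-test (the unequal-variance form, a robust
default the analysis does not otherwise constrain). When the readers chose
different index slices, masks are compared in-plane on Reader 1's index
slice — a deterministic convention recorded in the output.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `cutoffADC` | 1.37 | 1e-3 mm²/s | cancer-like / benign-like voxel split |
| `minMeanCoreArea` | 6.67 | mm² | SDAC forced-zero floor (mean over directions) |
| `maxRoiAreaCm2` | 7.50 | cm² | cohort exclusion limit on index-slice ROI area |
| `connectivity` | 26 | – | voxel neighborhood for region growing |
| `dilatePx` | 5 | px | in-plane dilation of the candidate/growth box |
| `maxCandidates` | 512 | – | cap on candidate thresholds (quantile-spaced) |
| `nFolds`, `nRepeats` | 5, 20 | – | cross-validation geometry |

## Down-sampling interpolated annotations

Readers annotate on interpolated display grids. Down-sampling to the
native DWI grid is defined through *contribution fractions*: the share of
each native pixel's footprint covered by in-ROI interpolated pixels, under
uniform rescaling of the two grids onto one physical extent. This is exact,
resolution-independent, conserves physical area, and reduces to block
averaging when the shapes divide evenly. Two inclusion rules are provided:
a fixed majority rule (fraction ≥ 50%, inclusive) and an adaptive rule that
scans all distinct fractions and keeps the cutoff whose down-sampled area is
closest to the area the annotation tool recorded, breaking ties toward the
larger mask (preserving lesion tissue at equal error). A down-sampling that
empties the ROI is an error, not a silent empty mask.

## The synthetic phantom

No public patient data exist for this problem, so the package ships a
generator whose defaults are the study conditions the pipeline targets: a
96×96×20 grid at 1.25×1.25×2.5 mm, fibroglandular background ADC
1.9 ± 0.2 (×10⁻³ mm²/s), ellipsoidal lesions, and a 29 benign / 34
malignant default cohort. Malignant cores are directionally anisotropic
(base ADC 0.9 with per-direction multipliers 1.0/1.35/0.75) with an
infiltrative rim (ADC 1.25) and a random necrotic/cystic high-ADC focus
covering 15–50% of the core — the focus is what degrades mean ADC as
necrosis does in patients. Benign lesions are isotropic (ADC 1.6, rim
1.7). Values the measurement chain needs but the study conditions do not
fix were chosen once as realistic and are not tuned: S0 levels 300
(background) / 700 (rim) / 1200 (lesion) a.u.; Rician noise σ = 15
(magnitude noise on all four volumes, the correct DWI noise model — at
b = 800 the background signal is ~65 a.u., so noise materially perturbs
ADC there, as in practice); in-plane semi-axes 3–9 mm and axial semi-axes
3–6 mm (index-slice areas ~0.1–2.5 cm², matching a small-to-medium lesion
cohort); per-lesion base-ADC jitter (SD 0.08 malignant, 0.15 benign) so
lesions differ as patients do. Two simulated readers annotate: Reader 1
every lesion-bearing slice with 1 px boundary jitter, Reader 2 only the
index slice with 2 px jitter (the blinded-reader surrogate). Jitter is
smooth radial noise applied to the signed boundary distance; it is capped
at half the lesion's in-plane radius, and an amplitude at or above the
inradius is rejected as degenerate. Anisotropy is modeled as
direction-dependent ADC multipliers rather than full tensors: the pipeline
only ever observes three directional ADC values, so this is the minimal
sufficient generative model.

What the phantom does *not* emulate: breast anatomy, EPI distortion, coil
sensitivity, lesion-shape irregularity beyond ellipsoids, and reader bias
(jitter is unbiased). Passing tests on phantoms therefore validate the
measurement and inference chain — forward-model inversion, segmentation
optimality, feature arithmetic, classifier calibration — not clinical
performance on patients.

## Numerical choices and degenerate inputs

* Indexing is 1-based throughout (R convention); slices run along the
  third array axis; areas are pixel count × dx·dy.
* Strict inequality ($auADC > t$) defines the grown set; seed ties go to
  the smallest column-major index.
* Negative raw signals are clamped to 0 at load with a logged count.
* Cross-validated probabilities are rounded at 1e-12 before ranking so
  that lesions with identical features score identically (IRLS returns
  probabilities equal only to ~1 ulp across folds).
* Complete separation in a training fold triggers a ridge-penalized refit
  (penalty 1e-6) with a warning.
* Wilcoxon signed-rank: zero differences are dropped; the exact null
  distribution is used for ≤ 25 untied non-zero differences, otherwise the
  normal approximation with continuity correction. McNemar: exact binomial
  on ≤ 25 discordant pairs, chi-square with continuity correction beyond.
* Both-empty masks define DSC = 0 and Jaccard = 0.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: scalar
ADC values against direct evaluation of the signal equation; region
growing against a dilation-to-fixpoint flood fill and, for component
counts, a repeated-fill labeling oracle; threshold selection against an
exhaustive per-threshold brute-force scan (on 16×16×5 volumes whose
dilated candidate box spans the grid, so the two semantics coincide);
binormal AUC against Monte-Carlo simulation at 10⁵ draws per class;
Wilcoxon/McNemar against sign-flip enumeration and the binomial tail; the
t-test against its type-I error over 10³ null simulations. End-to-end
checks run the full default cohort (63 lesions, two readers): on the
anisotropic cohort the combined classifier must beat the mean-ADC baseline
for both readers, and the model-based core sub-ROIs must agree across
readers at least as well as the hand ROIs. On matched null cohorts
(identical class parameters) every feature's empirical AUC, averaged over
three replicate cohorts, must lie within 0.5 ± 0.15; the averaging
controls the ~0.074 Mann-Whitney sampling SD of a single 63-lesion AUC
without widening the band.

## Known limitations

* The adaptive down-sampling rule assumes the annotation tool's recorded
  area is trustworthy; a wrong recorded area silently biases the cutoff.
* Threshold selection uses only the index-slice ROI; annotations on other
  slices do not constrain the model.
* Binormal moment matching is sensitive to heavy-tailed score
  distributions; the empirical AUC is reported alongside for that reason.
* With fewer lesions per class than folds, stratified folds cannot contain
  both classes and the classifier refuses to fit (by design).
* The phantom's ellipsoidal geometry makes segmentation easier than
  irregular clinical lesions; Jaccard values on phantoms are optimistic.
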