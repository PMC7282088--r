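# dwicadx

Model-based discrimination of benign from malignant breast lesions from
**directional diffusion-weighted MRI (DWI)**, for researchers building
non-contrast breast CADx pipelines.

Mean apparent diffusion coefficient (ADC) over a hand-drawn ROI — the
standard DWI discriminator — is corrupted by cystic/necrotic subregions,
boundary partial-volume, and reader variability. `dwicadx` implements a
model-based alternative built on three ideas:

1. **Directional analysis.** The three diffusion-encoding gradient
   directions $d \in \{r, p, s\}$ are processed separately:
   $ADC_d = (1/b)\,\ln(S_0/S_{d,b})$, and the region-growing field is the
   augmented map $auADC_d = S_0 \cdot ADC_d$.
2. **3D lesion models.** A topologically connected 3D volume model is grown
   on $auADC_d$ from a seed in the hand ROI, at the threshold that
   maximizes the Jaccard index between the model's index-slice
   cross-section and the hand ROI. The hand ROI is then split into a
   **lesion-core** (overlap with the model) and a **peri-lesion**
   (remainder) sub-ROI, per direction.
3. **Core/periphery features.** Voxels below the fixed cutoff
   $1.37 \times 10^{-3}\,\mathrm{mm^2/s}$ are cancer-like. The core feature
   **SDAC** is the standard deviation across the three directions of the
   core's cancer-like area (forced to 0 when the mean area is
   < 6.67 mm²); the periphery feature **ACMB** is the summed cancer-like
   minus benign-like area. Both orient toward malignancy and are combined
   by cross-validated logistic regression into a model-based classifier
   (MBC), evaluated with binormal ROC analysis
   ($AUC = \Phi(a/\sqrt{1+b^2})$, sensitivity read at 90% specificity)
   against the mean-ADC baseline.

The package also implements the inter-observer agreement analysis (Dice
coefficient of hand vs model-based ROIs, Wilcoxon signed-rank, McNemar,
ROI-size t-test), interpolated-annotation down-sampling, NIfTI I/O, and a
synthetic dense-breast phantom cohort generator (anisotropic malignant
lesions, Rician noise, two simulated readers) so the entire pipeline is
testable without patient data.

## Worked example

```r
library(dwicadx)

# one malignant phantom lesion and a simulated reader annotation
ph  <- generatePhantom(phantomSpec(label = "malignant", seed = 11))
ann <- simulateReaderROI(ph$truth, jitterPx = 1, seed = 2,
                         lesionId = "demo", readerId = "R1",
                         label = "malignant")
ann
#> LesionAnnotation 'demo' (reader R1, malignant): 4 slice(s), index slice 10 (88 px)

lf <- lesionFeatures(ph$series, ann)
round(lf$features[, c("sdac", "acmb", "mean_adc", "mean_jaccard")], 3)
#>    sdac  acmb mean_adc mean_jaccard
#> 1 4.774 18.75    0.933        0.794
```

The lesion's cancer-like core area varies across gradient directions
(SDAC = 4.8 mm², the anisotropy signature), its periphery holds more
cancer-like than benign-like tissue (ACMB = +18.8 mm²), and its mean ADC
(0.93 × 10⁻³ mm²/s) sits in the malignant range; the 3D model matched the
hand ROI with mean Jaccard 0.79 over directions.

A small end-to-end cohort (6 benign + 6 malignant phantoms, two simulated
readers, 2-fold CV):

```r
cfg <- runConfig(seed = 9, nRepeats = 5, nFolds = 2)
rep <- runPipeline(cfg, nBenign = 6, nMalignant = 6, dim = c(48, 48, 10))
rep$evaluation$summary
#>   reader_id  feature   auc auc_empirical sens_at_spec
#> 1        R1 baseline 0.928         0.889        0.843
#> 2        R1     sdac 1.000         1.000        1.000
#> 3        R1     acmb 1.000         1.000        1.000
#> 4        R1      mbc 0.985         1.000        0.985
#> ...
rep$agreement$meanDSCHand; rep$agreement$meanDSCCore
#> [1] 0.907
#> [1] 0.933
```

On this toy cohort every model-based feature separates the designed
anisotropic-malignant signal, and the algorithm-generated core sub-ROIs
agree between the readers better than their hand ROIs (DSC 0.933 vs
0.907). `runPipeline()` with its defaults runs the full 29 benign + 34
malignant study-scale cohort.

A thin command-line front end is included at `inst/cli/dwicadx.R`
(`simulate` and `run-all` subcommands).

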