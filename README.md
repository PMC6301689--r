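# pvcscore

Coronary artery calcium (CAC) volume scoring from CT, with partial volume
correction.

The amount of coronary calcium measured in CT is a strong predictor of
cardiovascular events, but the clinical volume score — count every voxel at or
above 130 HU, multiply by the voxel volume — is notoriously sensitive to
partial volume effects: with 3 mm slices, a dense calcification smears its
intensity into neighbouring voxels and can appear two to three times its true
size, while a faint one may vanish entirely. The resulting interscan
variability can push patients across risk-category boundaries.

`pvcscore` implements, alongside the clinical score (C-CS), a
partial-volume-corrected score (PVC-CS) that models each lesion together with
its local background:

1. **Detection.** Lesions are the 26-connected components of the voxel set at
   or above 130 HU.
2. **Extension.** Voxels above 90 HU that are 26-connected to a lesion may
   still contain calcium. They are kept only within *d*₁ of the initial
   segmentation, where *d*₁ is the largest interior distance of the initial
   mask (both distance transforms are anisotropy-corrected, in mm).
3. **Background.** The non-calcification voxels within *d*₂ of the
   calcification volume, where *d*₂ is its largest interior distance.
4. **Per-lesion threshold.** A two-component Gaussian mixture is fitted to the
   pooled calcification + background intensities by EM, and the threshold is
   set from the background component:

   Threshold = μ_B + FWHM_B / 2 = μ_B + √(2 ln 2) · σ_B

5. **Fractional scoring.** Every calcification voxel above the threshold
   contributes its estimated calcium fraction
   PVC_i = (X_i − X_min) / (X_max − X_min), and

   Volume_CAC = Σᵢ PVC_i · Volume_voxel

Because true lesion volumes are unknowable in patient data, the package also
ships a **digital phantom simulator**: cylindrical and circular-segment
hydroxyapatite inserts (98.2/21.2/0.8 mm³ and 62.8/24.6/9.1 mm³ at
800/400/200 mg/cm³) rasterised analytically on a supersampled grid, blurred
with an in-plane PSF and optional transverse motion (10/30 mm/s), and
block-averaged to a 3 mm slice grid — the partial volume effect arises from
the averaging itself. Analytic ground truth comes with every simulated
acquisition, and agreement statistics (Bland–Altman limits of agreement,
ICC(2,1) with an F-based confidence interval) support paired-reconstruction
reproducibility studies.

It is aimed at researchers developing or validating calcium quantification
methods who need a fully controlled, desk-scale test bed.

## Worked example

Simulate a noisy acquisition of two cylindrical inserts — a dense 98.2 mm³
(800 mg/cm³) and a faint 21.2 mm³ (200 mg/cm³) — in a 50 HU background, then
score it:

```r
library(pvcscore)
spec <- phantomSpec(
  inserts = list(cylinderInsert(diameter = 5, length = 5, density = 800),
                 cylinderInsert(diameter = 3, length = 3, density = 200,
                                center = c(12, 0, 0))),
  backgroundHU = 50, noiseSigma = 10, seed = 7)
sim <- simulateAcquisition(spec)
result <- scoreScan(sim$volume)
result
#> ScanResult: 2 lesion(s)
#>   total C-CS  231.84 mm^3
#>   total PVC-CS 132.84 mm^3
lesionScores(result)[[1]]
#> Lesion 1: threshold 64.3 HU, C-CS 204.48 mm^3, PVC-CS 110.25 mm^3
lesionScores(result)[[2]]
#> Lesion 2: threshold 67.5 HU, C-CS 27.36 mm^3, PVC-CS 22.58 mm^3
```

The true volumes are 98.2 and 21.2 mm³. The clinical score inflates the dense
insert to 204.5 mm³ (ratio 2.08) — every voxel its intensity bleeds into
counts fully — while the corrected score lands at 110.3 mm³ (ratio 1.12). The
per-lesion threshold of 64.3 HU comes from the fitted background component
(μ_B = 51.2 HU, σ_B = 11.2 HU, consistent with the 50 HU medium and 10 HU
noise):

```r
lesionScores(result)[[1]]@em
#> 2-component Gaussian mixture: B ~ N(51.2, 11.2^2), F ~ N(540.6, 360.5^2)
#>   weights 0.759/0.241, 9 iterations, converged: TRUE
```

Replica phantoms (`makeCeoraSpec()`, `makeSatiSpec()`),
`runPhantomExperiment()` for repeated-acquisition tables, and
`runKernelAgreementStudy()` for paired sharp/soft reconstruction agreement
round out the evaluation tool set. A thin command-line front end lives in
`inst/cli/pvcscore.R` (`simulate`, `score`, `evaluate` subcommands; NIfTI and
MetaImage I/O).

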