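---
title: "Partial-volume-corrected calcium scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-volume-corrected calcium scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcscore)
```

## The problem

Coronary artery calcium is quantified clinically by thresholding a CT volume
at 130 HU and reporting the volume of the supra-threshold voxels (C-CS). At
calcium-scoring slice thicknesses (3 mm) a voxel is far larger than the
structures of interest, so most lesion voxels are only partially filled with
calcium. Dense lesions bleed intensity into their surroundings and are
overestimated; faint lesions hover near the threshold and flicker in and out
between scans. Both effects degrade the reproducibility on which risk
categorisation depends.

`pvcscore` implements a corrected score (PVC-CS) that treats voxel intensity
as a linear mixture of calcium and background and integrates the estimated
calcium *fraction* instead of counting voxels.

## The scoring model

For each lesion (a 26-connected component of the ≥ 130 HU set):

1. **Extension.** Voxels with intensity above 90 HU that are 26-connected to
   the lesion are candidate calcium. To keep streaks and noise chains out,
   candidates farther than $d_1$ from the initial mask are discarded, where
   $d_1$ is the largest interior distance of the initial mask — the depth of
   its "center". The calcification volume is the initial mask plus the
   retained extension.
2. **Background.** Let $d_2$ be the largest interior distance of the
   calcification volume. The background is every non-calcification voxel
   within $d_2$ of it ($d_2 \ne d_1$ in general, since they are depths of
   different masks). Voxels belonging to *another* lesion's calcification
   volume are excluded so calcium never contaminates the background sample;
   shared background between nearby lesions is allowed.
3. **Threshold.** A two-component univariate Gaussian mixture is fitted by EM
   to the pooled calcification + background intensities, and the per-lesion
   threshold is placed half a FWHM above the background mean:
   $$\mathrm{Thr} = \mu_B + \tfrac{1}{2}\,\mathrm{FWHM}_B
                  = \mu_B + \sqrt{2\ln 2}\,\sigma_B .$$
4. **Fractional scoring.** Over the supra-threshold calcification voxels,
   $$\mathrm{PVC}_i = \frac{X_i - X_{\min}}{X_{\max} - X_{\min}},\qquad
     V_{\mathrm{CAC}} = \sum_i \mathrm{PVC}_i \cdot V_{\mathrm{voxel}} .$$

Assumptions worth stating: intensity is affine in local calcium fraction
(valid for a single-energy acquisition without beam hardening); each lesion's
neighbourhood is well described by one background component; and the
brightest voxel of a lesion is (nearly) pure calcium, since $X_{\max}$
anchors the scale. The last assumption is the model's weakest point for small
or fast-moving lesions, where no voxel is pure.

### Distance conventions

All distances are voxel-center to voxel-center in millimetres, computed with
an exact anisotropic Euclidean distance transform (separable
lower-envelope-of-parabolas algorithm with per-axis spacing). A distance
measured "in voxels" would be meaningless under the 7.5:1 anisotropy of a
0.4/0.4/3 mm grid. The interior distance of a mask voxel is its distance to
the nearest *non-mask* center, so a single isolated voxel has depth equal to
the smallest spacing; the exterior distance is measured to the nearest mask
center. The extension bound is applied as exterior distance ≤ $d_1$ and the
background bound as exterior distance ≤ $d_2$, each with a $10^{-9}$ mm slack
against floating-point ties.

### EM details

The mixture is initialised deterministically from the two masks: background
component from the background voxels' sample moments, foreground from the
calcification voxels', weights proportional to voxel counts — an informative
start that makes scoring reproducible without restarts. The E-step works in
log space (log-sum-exp); iteration stops when the log-likelihood gain drops
below `emTol` (default 1e-6) or at `emMaxIter` (200). Component SDs are
floored at 0.5 HU; hitting the floor, or two means closer than the narrower
component's SD, flags the fit as degenerate (the fit is still returned — a
two-point lesion legitimately yields two spikes). Components are relabeled so
$\mu_F \ge \mu_B$. Thresholds are never shared across lesions.

### Edge cases

* Threshold above the lesion maximum: the lesion scores 0 with a warning.
* $X_{\max} = X_{\min}$ (single-intensity lesion): $\mathrm{PVC}_i = 1$; the
  voxel exceeded the detection threshold, which is positive evidence of
  calcium.
* The definition of $X_{\min}$ is genuinely ambiguous — "minimum of the
  segmented lesion" can mean the supra-threshold subset or the whole
  calcification mask. The default (`xminMode = "supra_threshold"`) uses the
  scored subset, so $X_{\min} \ge \mathrm{Thr}$ by construction;
  `"literal_lesion_min"` and `"threshold"` expose the alternatives.
* Lesions failing to score (degenerate input) are reported in the scan
  status and excluded from totals rather than aborting the scan.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `detectionHU` | 130 | HU | the clinical detection threshold |
| `extensionHU` | 90 | HU | conventional lower bound for possible calcium |
| `minLesionVoxels` | 1 | voxels | no minimum in the scoring definition; set 3 for Agatston-style conventions |
| `emTol` / `emMaxIter` | 1e-6 / 200 | — | converges in < 20 iterations on realistic lesions |
| `sigmaFloor` | 0.5 | HU | prevents likelihood spikes on tied intensities |
| `xminMode` | supra_threshold | — | see above |

Both thresholds are configuration, not constants: analyses of detection below
130 HU only require a different `RunConfig`.

## What the phantom simulator emulates — and what it does not

The generator works entirely in the image domain: analytic insert shapes
(cylinders; circular segments for the half-cylindrical artery inserts) are
rasterised at `supersampling`× the reconstruction grid with fractional
occupancy (3×3 in-plane sub-sampling, exact axial overlap), converted to HU
by an affine hydroxyapatite calibration, optionally blurred along the
transverse axis by a box kernel of width *velocity × exposure time* (motion),
blurred in-plane by a Gaussian PSF, block-averaged to the reconstruction grid
— which is precisely where the partial volume effect appears — and finally
given i.i.d. Gaussian noise. Replica specs reposition the whole phantom by a
random sub-voxel translation per acquisition (uniform within ±0.2 mm
in-plane, ±1.5 mm axially: half a voxel per axis), which drives realistic
interscan variability at 3 mm slices.

Defaults chosen where the emulated protocol leaves gaps, fixed once:

* in-plane reconstruction spacing 0.4 mm (typical calcium-scoring
  reconstruction; the protocol fixes only the 3/3 mm slice grid, or 3/1.5 mm
  for chest-CT-like overlapping reconstructions);
* HA→HU slope 1.6 HU/(mg cm⁻³), placing 200/400/800 mg/cm³ at 320/640/1280
  HU — within realistic 120 kVp ranges and all above 130 HU before blurring;
* PSF σ 0.6 mm (≈ 1.4 mm FWHM, a standard body kernel); the paired
  "sharp"/"soft" reconstruction surrogates use σ 0.4 mm with 18 HU noise and
  σ 0.8 mm with 8 HU noise, both derived from one noiseless master raster so
  the pair shares its acquisition exactly;
* girth (extension-ring) effects modelled purely as noise: 10/15/20 HU for
  none/M/L — the rings do not alter the insert geometry, they degrade photon
  statistics;
* exposure time 0.35 s per slice for the motion blur width;
* background 0 HU for the thorax-insert phantom, 50 HU (blood-equivalent
  resin) for the moving-artery phantom;
* the circular-segment radius is 2.0 mm — the value that reproduces all
  three printed insert volumes (62.8/24.6/9.1 mm³) exactly — with inserts
  mutually rotated ±60° about the artery axis and spaced 18 mm axially so
  that each remains an individually resolvable lesion, as in the physical
  phantom;
* of the two printed figures for the detectable segment-phantom total
  (87.6 vs 87.4 mm³ with the small low-density insert undetected), the
  arithmetic sum 62.8 + 24.6 = 87.4 is used.

Not modelled: projection-domain physics (no sinograms, filtered
backprojection, beam hardening, streaks), spectral/dual-energy effects,
through-plane motion, heterogeneous lesion composition, and anatomy
(bone, aorta) that real chest CT scoring must exclude — lesion identification
in patient data remains a manual or upstream task, and this package scores
whatever exceeds the threshold inside an optional region-of-interest mask.
Consequently, passing phantom tests demonstrates correct behaviour of the
scoring chain under controlled partial-volume, noise and motion conditions;
it does not certify accuracy on scanner data, where reconstruction kernels,
artifacts and tissue heterogeneity add effects the simulator deliberately
omits. Simulated scores are also sensitive to where an insert falls relative
to the slice grid — the same alignment sensitivity the 3 mm protocol shows in
practice — so quantitative simulation results are tied to the replica
geometry.

## Evaluation machinery

`runPhantomExperiment()` aggregates repeated seeded acquisitions into the
conventional per-density tables (measured/true ratios; median and range over
acquisitions, with the sample median for even counts). Detected lesions are
attributed to ground-truth inserts by largest fractional-occupancy overlap.
"Totals" are per-HA-density detected totals, the grouping in which such
phantom results are conventionally reported.

`blandAltman()` uses differences *a − b* (soft − sharp by convention), bias ±
1.96 × sample SD (n − 1). `iccAgreement()` computes ICC(2,1) — two-way random
effects, absolute agreement, single measurement — from the mean-squares
decomposition, with the F-distribution confidence interval; paired
reconstructions are random "raters" of one quantity, and absolute agreement
is what reproducibility requires. Min–max scaling for cross-method
comparison divides by the maximum of the *soft-kernel* volumes of the same
method (per-method scaling; scaling across methods would let the method with
the larger dynamic range dominate).

## Problem sizes

The test suite validates the compiled primitives against brute-force oracles
on 50 random grids up to 16³; EM parameter recovery on 20 seeded two-Gaussian
samples of n = 1000; and the behavioural claims on 5 seeded acquisitions per
replica phantom (3 for the motion condition) plus 50 paired sharp/soft
reconstructions of randomised single-insert phantoms at supersampling 4.
Replica phantoms use supersampling 8, at which the rasterised ground truth
matches the analytic volumes to well under 1 %.

## Known limitations

* $X_{\max}$ is a single-voxel extreme and inherits its noise; a
  high-quantile anchor would be more robust but would change the score's
  definition.
* PVC-CS systematically underestimates low-density lesions: their true
  interior intensity sits near the scaling range's lower end, so genuine
  calcium voxels receive fractions well below 1.
* Lesions visible in only one slice are strongly alignment-dependent under a
  contiguous 3 mm protocol; overlapping reconstructions (3/1.5 mm) mitigate
  but do not remove this.
* The EM threshold assumes a unimodal local background; adjacent bright
  structures violate this and should be excluded via the ROI mask.
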