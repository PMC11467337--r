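---
title: "Methods: synthetic myeloblast tomograms, morphometry, and patient-level screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic myeloblast tomograms, morphometry, and patient-level screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Holotomography reconstructs the three-dimensional refractive index (RI)
distribution of a living cell. Because the RI of cytosol scales linearly with
the local biomolecular mass concentration, an RI tomogram is simultaneously a
shape measurement and a quantitative dry-mass map. In acute myeloid leukemia,
mutations of the *NPM1* gene displace nucleophosmin from the nucleolus to the
cytoplasm, and this relocation leaves subtle but measurable traces in
myeloblast morphology: a rounder, relatively larger nucleus, a slightly less
spherical cell outline, and shifted RI values in the nucleolus and cytoplasm.

`holoblast` implements the full quantitative chain for this problem:

1. a **seeded phantom generator** producing myeloblast RI tomograms whose
   per-cell statistics follow the group distributions reported for wild-type
   (`WT`) and mutant (`MUT`) blasts;
2. **rule-based segmentation** into cytoplasm, nucleoplasm, nucleolus and
   lipid droplets;
3. **morphometry**: volume, iso-surface area, sphericity
   $\psi = \pi^{1/3}(6V)^{2/3}/A$, mean RI, and dry mass through the specific
   refractive increment;
4. **group statistics** with the Mann-Whitney U test and fixed significance
   tiers;
5. a configurable **3D tail-body-head CNN** for single-cell genotype
   prediction; and
6. **patient-level screening**: the positive prediction ratio per patient,
   its ROC across thresholds, and the operating points.

Because the study's patient tomograms are not publicly deposited, the
generator is a first-class, tested component: it defines the conditions under
which every downstream module is validated.

## Phantom model

### Shapes

Cell and nucleus outlines are star-convex radius fields
$R(u) = R_0\,E(u)\,\max\{0.15,\,1 + a f(u)\} + R_0\,c\,w(u)$ over directions
$u$, with four ingredients:

* $f(u)$: a smooth random lobe field (sum of von Mises-Fisher bumps,
  concentration 8), standardized to zero mean and unit variance;
* $w(u)$: a dense cosine corrugation field (8 random plane waves, angular
  frequencies 14-22), emulating nuclear envelope folding; its height is
  capped at 24% of the base radius so fold slopes stay near the value that
  doubles surface area without producing sub-voxel spikes;
* $E(u)$: a determinant-one ellipsoid factor with random orientation,
  providing elongation/flattening;
* beyond the star-convex regime, spherical *indentations* ("bites") grow at
  three fixed random boundary directions, producing the kidney and lobed
  morphologies that star-convex fields cannot reach.

All four are controlled by a single irregularity parameter $s \in [0, 2]$
($s \le 1$: lobes + corrugation + ellipsoid scale together; $s > 1$:
indentation radius grows). The generator *calibrates* $s$ per cell by a
secant iteration against the **measured** sphericity of the voxelized shape
and trims $R_0$ to the target volume (within 0.5%). Because calibration and
downstream morphometry use the same estimator, estimator bias cancels in
round-trip comparisons; this is the key design decision that makes the
parameter-recovery tests meaningful.

The nucleus shares the cell's lobe field mixed with an independent component
(weight 1.2) and is voxelized inside the cell interior (one-voxel erosion),
so its lobes follow the cell while its folds remain its own; where it presses
against the membrane it flattens, as real blast nuclei do. Because a nucleus
occupying ~40% of the cell cannot be arbitrarily irregular, the sphericity
floor of the nested shape model is about 0.46; sampled nucleus sphericities
are truncated there and the truncated-normal location is adjusted
numerically so the group *mean* is preserved exactly. Nucleoli are spheres
(their sphericity is not reported in the source statistics), packed without
overlap inside the nucleus; lipid droplets, when drawn, are small
high-RI spheres in the cytoplasm.

### Parameter sampling

Each continuous parameter is drawn from a truncated normal with the reported
group mean and sd (symmetric +-2 to +-2.5 sd bounds where geometry permits,
mean-adjusted asymmetric bounds otherwise). Three structural choices matter:

* **Nucleus volume is derived, not drawn**: the N/C volume ratio and the
  cell volume are sampled and $V_{nuc} = r_{NC} V_{cell}$. Sampling both
  volumes independently would inflate the mean measured ratio by Jensen's
  inequality (about +16% at the reported dispersions); with the ratio
  sampled directly, the recovered ratio mean matches the target while the
  nucleus-volume mean becomes emergent (about 193 fL vs the reported
  201 fL for mutants -- within sampling noise of the study's own internal
  consistency).
* **RI values are coupled**: nucleoplasm RI = cytoplasm RI + positive
  offset, and nucleolus RI = nucleoplasm RI + positive offset, with offset
  moments chosen so every marginal keeps its reported mean and sd. This
  encodes that whole-cell protein content shifts compartments together,
  guarantees the ordering nucleolus > nucleoplasm > cytoplasm that the
  images show, and keeps the nucleoplasm/cytoplasm contrast segmentable
  (independent draws would leave ~9% of cells with no contrast at all).
* **Patients are hierarchical**: 25% of each parameter's variance sits at
  the patient level (a dominant clone makes a patient's cells resemble each
  other); with the patient fraction at 0, sampling collapses to i.i.d.
  draws. Mutant patients carry a variant allele fraction drawn uniformly
  from 0.2-0.5 (the study reports only that low-VAF cases misclassify more
  often, not a distribution).

RI texture inside each compartment is a Gaussian random field smoothed at
0.5 um, standardized within the region and scaled to sd 0.0015, then
mean-corrected so region-mean RI values are exact before noise. Sensor noise
is additive Gaussian (default sd 0.001), clamped at +-3 sd.

Defaults that the source does not state and that were fixed once:
medium RI 1.337 (phosphate-buffered saline), voxel pitch 0.156 um lateral /
0.312 um axial (typical for the instrument class), nucleolus count uniform
on 1-3, lipid droplets in 15% of cells. The generator does **not** model the
optical transfer function of tomographic reconstruction (no missing-cone
elongation, no halo), staining appearance, or multi-cell fields; passing
tests therefore validate the analysis chain, not robustness to those
acquisition artifacts.

## Morphometry

Volume is voxel count times physical voxel volume. Surface area meshes the
0.5 level set of the binary region by marching tetrahedra in physical units;
raw lattice meshes overestimate curved areas by up to ~25% (staircase
effect), so each facet's area is weighted by $|\cos\theta|$ between the
facet normal and the gradient of a Gaussian-smoothed copy of the mask
(sigma = 1.25 lateral voxels, floored at 0.8 voxel axially). The weighting
is exact for flat axis-aligned faces and cancels the staircase inflation on
curved surfaces; against closed forms the estimator is within 3% for a
digital ball of radius 20 voxels, a cube (psi 0.806 +- 0.01 at side 128),
and a 2:1:1 prolate spheroid (psi 0.929 +- 0.02), including anisotropic
voxels, which are meshed in physical units rather than resampled.

Dry mass uses the linear RI-concentration relation
$c = (n - n_m)/\alpha$ per voxel and $m = \sum c\,v_{vox}$. The specific
refractive increment defaults to $\alpha = 0.185$ mL/g, back-derived from
the reported sensitivity of 5.4 fg/fL per 0.001 RI contrast; it is a
configurable argument everywhere it enters. Negative voxel contributions are
permitted (they occur under noise) and a region with negative total mass is
flagged rather than clipped. Lipid droplets are excluded from the cytoplasm
mean RI but included in whole-cell dry mass; the source does not state its
convention, so this one is documented and configurable through the region
argument.

The N/C ratio is computed both from voxel volumes (3D) and from axial
projections (2D), the latter mirroring the en-face view of conventional
microscopy -- the comparison that makes the 3D-only group difference
visible.

## Rule-based segmentation

The interactive pixel classification of the original pipeline is replaced by
deterministic rules so that segmentation is testable against ground truth:

1. background: RI below medium + max(2 x noise sd, 0.004); the cell is the
   largest connected component after closing/opening, hole-filled;
2. lipid: components above RI 1.39 -- segmented *first*, because the lipid
   RI spike would otherwise capture the Otsu split;
3. nucleus: Otsu threshold learned on interior voxels only (>= 0.45 um from
   the membrane, excluding lipid), applied to the whole cell; largest
   component, hole-filled. No presmoothing: the nuclear envelope is
   convoluted, and smoothing erodes it faster than it suppresses noise
   (Dice drops from ~0.97 to ~0.84 with 0.3 um smoothing); isolated
   noise voxels are absorbed by the connected-component and hole-filling
   steps instead;
4. nucleoli: components inside the nucleus above the nucleoplasm mean +
   2.5 noise-corrected texture sds, iterated once so the nucleoplasm
   statistics exclude the nucleolar tail. The threshold multiplier is 2.5
   rather than 2 because at 2 the intra-nucleoplasm texture field produces
   coherent false-positive blobs.

On a default-parameter phantom the per-region Dice against ground truth is
>= 0.95 without noise and the cell region stays >= 0.90 at the default
sensor noise. Cells whose sampled nucleoplasm/cytoplasm or
nucleolus/nucleoplasm contrast falls in the lower tail remain genuinely hard
for any threshold rule; parameter-recovery analyses therefore use the
ground-truth masks, and the rule-based path is validated separately.

## Group statistics

`mann_whitney_u()` computes U from midranks; p-values are exact (enumeration
over group assignments of the observed midranks, which handles ties
correctly) for total n <= 20 and otherwise use the normal approximation with
tie correction and continuity correction. Exhaustively over every achievable
U, the exact and approximate two-sided p-values agree within 0.01 for equal
group sizes of 9-12; at n = 8 the approximation has an intrinsic worst case
of 0.0109, occurring only where the exact two-sided p exceeds ~0.38 -- the
whole significance-relevant range stays within 0.01. Two-sided p-values are used
throughout; the significance tiers are fixed at `*` p < 0.01, `**` p < 0.001,
`***` p < 0.0001, and no multiple-testing correction is applied (matching
the source analysis). Observations are per-cell, pooled across patients with
no clustering adjustment; with ~1,000 cells per group from ~25 patients the
effective sample size for patient-level inference is much smaller than the
nominal n, so tiers should be read as descriptive of this dataset
convention, not as patient-level inference.

## Classifier

The network follows the multi-resolution tail-body-head design: the tail
downsamples by 2x2x2 max pooling, the body upsamples by nearest-neighbour
resizing and concatenates each upsampled map with the first equal-resolution
tail features, and the head downsamples again. Residual bottlenecks
(1x1x1 shortcut summed with a 1x1x1 -> 3x3x3 -> 1x1x1 reduced-channel path)
precede every resampling step, and every convolution is preceded by instance
normalization and leaky-ReLU pre-activation. Global average pooling feeds a
latent feature layer (default 264) ahead of the two-class output.

The published network's exact channel widths are not public (only its
80.8M-parameter total), so widths and stage counts are configuration;
`count_parameters()` reports the closed-form parameter count of any
configuration and is verified against the allocated tensors. The training
recipe keeps the published hyperparameters: Adam (first moment decay 0.5,
second 0.999), initial learning rate 5e-4, batch 16, cosine annealing with a
32-epoch period, and inverse-class-size loss weights. Two readings were
fixed once: "learning rate decay 1e-4" is implemented as decoupled weight
decay (the standard reading alongside Adam; a multiplicative schedule is
available), and the cosine period is in epochs. Every epoch presents each
training image twice -- original and randomly augmented (Gaussian noise,
integer translation, in-plane flips only, rotation about the optical axis) --
and the checkpoint with the highest training + generalization accuracy is
kept; training accuracy is taken from the epoch's own forward passes.
Exact output ties predict wild-type, so screening errs toward confirmatory
genetic testing rather than mutation calls.

Everything runs on CPU at the test preset (input 32x32x16, one stage per
component, base 8 channels, ~8k parameters; convolutions use
single-precision kernels). The full 160x160x72 preset is the documented
target topology and is GPU-scale; it is excluded from the test suite. The
classifier correctness is anchored by finite-difference gradient checks and
hand-computed loss values; its learning ability is demonstrated on a toy
cohort (100 cells per class, sphericity means 0.45 vs 0.60 for both cell
and nucleus, rendered at 64x64x32 and block-averaged to the network input --
rendering at the input resolution directly cannot realize sphericities this
low). The study's real-data accuracies (76.0% single-cell, and the 20.4% /
25.8% misclassification rates) depend on the non-deposited patient data and
weights and are deliberately not targets.

## Patient-level screening

For each patient the positive prediction ratio r is the fraction of cells
called mutant. A patient is screened positive when r >= t (closed rule; this
choice makes the published thresholds 93.3% and 39.2% fall inside the
achieving threshold intervals). Sweeping t over all observed ratios plus
infinity yields the ROC; the area is computed by trapezoidal integration
with integer accumulation, which makes it *exactly* equal to the
pair-concordance statistic with ties counted one half. Operating points are
reported with the half-open threshold interval that attains them, because a
single threshold value is an arbitrary representative of that interval.
The worked eight-patient example in the tests (WT ratios 0.10/0.20/0.30/0.45,
MUT 0.40/0.94/0.95/0.96) is a *constructed* ratio set consistent with all
three published ROC numbers; per-patient ratios themselves are not printed
in the source.

## Problem sizes and numerical choices

* Parameter-recovery runs use 200 phantoms per genotype on a 96x96x48 grid
  (15 um field of view), the scale at which means are compared within three
  standard errors; the default rendering grid is 160x160x72.
* Shape calibration tolerance is 0.006-0.008 in sphericity and 0.5% in
  volume; the secant solver falls back to the closest evaluation when the
  discrete sphericity-irregularity curve is non-smooth at coarse grids.
* Instance-norm epsilon is 1e-5; Adam epsilon 1e-8; weights are
  He-initialized.
* Degenerate inputs are explicit: empty fields and two-cell fields are
  errors in segmentation; absent regions yield missing-value rows, not
  zeros; fully tied rank tests return p = 1 with a degeneracy flag.
* All randomness flows from one seed through named substreams
  (`derive_seed()`), so any subset of a cohort can be re-rendered
  reproducibly; training is reproducible up to floating-point summation
  order.

## Known limitations

* No optical forward model: tomograms are geometric renderings with additive
  noise; reconstruction artifacts (missing cone, halo) are absent.
* The nested-shape sphericity floor (~0.46) compresses the lower tail of
  nucleus sphericity relative to a normal distribution; group means are
  preserved exactly, dispersions shrink by up to ~20%.
* Printed group statistics drive the generator; joint correlations beyond
  those listed above are not modeled.
* The rule-based segmenter assumes a single cell per field of view and
  breaks down gracefully (explicit errors) otherwise.
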