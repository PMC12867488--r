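---
title: "Methods: rule-based lesion volumetry for cleared-brain light sheet imaging"
author: "strokevol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based lesion volumetry for cleared-brain light sheet imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokevol)
```

## The problem

Photothrombotic stroke produces a focal cortical infarct whose volume is the
primary outcome of many experimental designs. In optically cleared whole
mouse brains imaged by light sheet fluorescence microscopy (LSFM), the
ischemic core shows strong endogenous autofluorescence against healthy
tissue, so the lesion can be delineated in 3D without any exogenous label.
`strokevol` implements a rule-based segmentation of that autofluorescent
core, voxel-counting and slice-based volumetry, clearing-shrinkage
accounting, laser speckle contrast mapping of the acute perfusion deficit,
and the simple-regression statistics used to compare modalities. A seeded
phantom generator provides ground truth for all of it, so the entire
pipeline is testable on a desktop with no microscope data.

## The segmentation rule

Given a volume $I$ with voxel spacing $(s_z, s_y, s_x)$ in micrometres
(axis order $z,y,x$ everywhere; $z$ is the acquisition direction), the
workflow is:

1. **Contralateral threshold.** Choose a box ROI in the hemisphere opposite
   the lesion and take the nearest-rank $p$-th percentile of its intensity
   multiset as the global threshold $T$. Nearest rank (the value at rank
   $\lceil pn/100 \rceil$ of the sorted sample, no interpolation) is used
   because it always returns an observed intensity and is bit-reproducible
   across implementations. The default $p = 99$ sits above healthy-tissue
   fluctuation while capturing a $2\times$-contrast lesion; the percentile
   is fixed per cohort, which is what removes the operator from the loop.
2. **Binarization and vessel exclusion.** Foreground is $I \ge T$, followed
   by a morphological opening with a physical ball of diameter
   `detail_size_um` (default 30 µm), realised as an anisotropic voxel
   structuring element through the spacing. Structures thinner than the
   ball -- in particular bright vessels of ~10 µm calibre -- cannot contain
   it and are removed, while the lesion core (hundreds of µm across) is
   essentially untouched. `detail_size_um = 0` disables the opening.
3. **Component labelling and core selection.** Connected components under
   26-connectivity (default; 6 and 18 are available) are summarised by
   voxel count and physical centroid and sorted by descending size, ties
   broken by ascending centroid $z$ then discovery order. The infarct core
   is the largest component by default; a seed-point strategy (the scripted
   analogue of clicking the core) selects the component containing a given
   physical point instead.
4. **Bounded refinement (optional).** `refine_threshold()` moves $T$ by
   integer steps of 1% of the contralateral ROI's dynamic range (at most
   ±10 steps) and re-runs stages 2–3. The step size makes "minute
   adjustment" auditable: the delta is recorded in the parameter record
   along with every other setting and the realised threshold.

Volume is foreground voxel count times the voxel volume
$s_z s_y s_x\,\mu m^3 / 10^9$ (mm³). Slice-based estimates — the MRI and
serial-histology estimators — are $\sum_i A_i \times t$ with $A_i$ the
per-section infarct areas (mm²) and $t$ the slice thickness, or the
inter-section interval when sections are subsampled (e.g. 50 µm sections
read every 200 µm), matching how such series are analysed in practice.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `percentile` | 99 | – | above healthy fluctuation, below a 2× lesion; fixed per cohort |
| `detail_size_um` | 30 | µm | exceeds ~10 µm vessel calibre, far below lesion scale |
| `connectivity` | 26 | – | matches surface rendering of continuous structures |
| selection | largest | – | single contiguous infarct core; seed point available |
| refinement step | 1% of ROI range | intensity | bounded, recorded adjustment |
| LSCI window | 7×7 | px | standard spatial-contrast window |
| hypoperfusion cutoff | 0.30 | relative | explicit, configurable; no published value exists |

## The phantom generator

`phantom_spec()` describes a pre-clearing geometry: an ellipsoidal brain of
uniform background autofluorescence $b$ (100 arbitrary units), an
ellipsoidal lesion of mean $b \times$ `lesion_contrast`, straight tubular
vessels of fixed diameter at $b \times$ `vessel_contrast`, additive
Gaussian noise of SD `noise_sigma`$\times b$, and per-axis linear clearing
shrinkage `shrink_factors` applied to every length before voxelisation.
`default_phantom_spec(V)` sizes a mildly oblate lesion (1 : 0.8 : 0.8
semiaxes) to a target post-clearing volume $V$, places it in the $+y$
hemisphere, and builds the brain and grid around it, leaving the $-y$
hemisphere for the contralateral ROI.

Defaults are the study conditions used throughout the tests: 10 µm
isotropic voxels, lesion contrast 2.0, noise 0.1, twelve 10 µm vessels at
contrast 3.0, and anisotropic shrinkage (0.85, 0.80, 0.75), inside the
10–30% per-dimension band typical of solvent-based clearing. The
lesion-to-background contrast has no published value; 2.0 is a free
parameter chosen once as a conservative figure for a structure described as
clearly delineable, and the noise and vessel settings exercise exactly the
failure modes the rule is designed against (isolated supra-threshold noise,
bright thin distractors). Two phantom choices deserve explanation:

* **Vessels spare a 25 µm perilesional halo.** A vessel tangent to the
  lesion surface would be absorbed into the core by the dilation half of
  the opening, making "did vessels leak into the core" ill-posed at the
  label level. The halo (larger than the 15 µm opening radius at default
  settings) keeps the truth labels disjoint by construction, so vessel
  exclusion can be scored exactly.
* **Speckle is ensemble-averaged, not spatially filtered.** Post-stroke and
  baseline stacks are fully developed speckle with per-pixel intensity
  distributed Gamma($M$), i.e. the average of $M$ independent exponential
  speckle realisations, whose contrast is exactly $1/\sqrt M$. This gives
  independent pixels (so windowed SD/mean is an unbiased contrast
  estimator) and lets the hypoperfused region hit an arbitrary target
  contrast ratio exactly ($M_{\text{post}} = M/\text{ratio}^2$), which
  integer-sized spatial filters cannot. `base_contrast = 1` degenerates to
  raw exponential speckle with $k = 1$.

What the phantoms deliberately do **not** model: light-sheet PSF and stripe
artifacts, intensity inhomogeneity across the field, Poisson (signal-
dependent) noise, curved or branching vasculature, irregular lesion
borders, and hemodynamic speckle physics. Passing tests therefore
demonstrate that the *rules* are implemented correctly and behave as
claimed under controlled contrast/noise/geometry — not that the default
percentile would be optimal on any given microscope's data, which is why
the percentile and ROI remain required, cohort-level inputs.

## Derived modalities

* **MRI-like stacks** (`derive_mri`): the truth lesion dilated by an edema
  halo (`edema_dilation_um`, a morphological dilation radius) and collapsed
  into coarse slices. Per-slice areas use the partial-volume fraction of
  each slab, so $\sum A_i t$ equals the dilated volume up to slab
  discretisation; with zero edema and native thickness it reproduces the
  voxel count exactly. Any positive edema strictly overestimates truth —
  the documented direction of early MRI volumetry.
* **Histology-like series** (`derive_histology`): true cross-sections
  sampled every `interval_mm`, with the interval recorded as the volume
  multiplier. A lesion thinner than the interval can be missed entirely;
  that undersampling failure mode is kept, not papered over.
* **Speckle pairs** (`derive_speckle`): as above; the hypoperfused region
  defaults to the lesion's dorsal footprint projected onto the camera grid.

## Numerical choices and degenerate inputs

* Axis order is fixed `(z, y, x)` and asserted in every constructor; TIFF
  input *requires* explicit spacing (an axial step of 10–15 µm silently
  replaced by an in-plane default would corrupt every volume), NIfTI
  spacing is header mm converted to µm.
* Intensities are never rescaled on read; integer TIFF samples round-trip
  bit-exactly, float samples at 32-bit precision.
* Nearest-rank percentile, sample SD with $n-1$, and OLS closed forms are
  each stated once and tested against independent references
  (`quantile(type = 1)`, hand-computed windows, `lm()`).
* Orientation resampling permutes axes and linearly interpolates
  intensities onto the coarser axial grid; masks are never interpolated —
  segmentation is re-run on resampled intensities. The new axial step must
  be at least the native spacing (no invented resolution).
* Discrete openings by growing Euclidean balls are anti-extensive and
  monotone only up to ball voxelisation (a few boundary voxels can flicker
  between sizes, the balls not being perfectly nested on the grid);
  threshold monotonicity is exact.
* Empty results are values, not errors: an empty mask has volume 0, a
  volume with no surviving supra-threshold structure yields an explicit
  "no lesion found" segmentation, and an all-zero slice table sums to 0.
  Empty *inputs* (no sections, empty ROI) are rejected with messages naming
  the offender.
* Component ties are broken by centroid $z$ then discovery order;
  `p`-values are clamped into $(0, 1]$ so a perfect fit reports the
  smallest representable positive value rather than 0.

## Shrinkage accounting

Clearing shrinks each dimension by ~10–30%; `shrinkage_percent()` computes
per-axis percent change from pre/post measurements and flags values inside
that band. `correct_for_shrinkage()` divides a measured volume by the
product of the linear factors (20% isotropic shrinkage → factor
$1/0.8^3 \approx 1.95$, i.e. the familiar "twofold" volume reduction).
Correction is **off by default**: comparisons across modalities are made in
post-clearing space, because shrinkage is consistent within a brain and
relative lesion size is preserved — correcting would only rescale both axes
of the regressions the package reports.

## Problem sizes used in the shipped tests

The test suite and the acceptance script regenerate everything from seeds:
unit tests use ~0.9M-voxel phantoms; the orientation-concordance experiment
uses ten phantoms with truth volumes 0.05–1.0 mm³ on 10 µm grids (up to
~15M voxels each), segmented independently in dorsal (10 µm axial step) and
sagittal (15 µm step) orientations; parameter recovery uses twenty phantoms
over the same volume range at noise 0.1 and contrast 2.0. These sizes give
≥23 voxels per lesion semiaxis, the regime where voxelisation error is
comfortably below the 2–5% tolerances being asserted.

## Known limitations

* The lesion model is a single contiguous ellipsoid; multi-focal or highly
  irregular infarcts exercise the component-selection machinery but have no
  synthetic ground truth here.
* "Surface detail size" is interpreted as an opening diameter; rendering
  software implements proprietary size filters whose exact correspondence
  is unknowable, so a minimum-component-volume filter would be a reasonable
  alternative interpretation (the opening is the one implemented).
* Spatial windowed contrast averaged over frames is the default LSCI
  reading; temporal per-pixel contrast is exposed as an alternative mode.
* No atlas registration or anatomical localisation; volumes are reported in
  the acquisition frame.
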