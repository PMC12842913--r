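---
title: "Scan-coverage and image-noise QA for low-dose chest CT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-coverage and image-noise QA for low-dose chest CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctqa)
```

## The problem

Low-dose CT (LDCT) lung-cancer screening produces large volumes of scans
whose acquisition quality is rarely audited systematically. Two acquisition
properties matter and are measurable fully automatically from the images
alone:

* **Scan-range coverage.** Every axial slice acquired beyond the lung
  parenchyma (*overscanning*) is unnecessary radiation; a lung that reaches
  the first or last slice (*underscanning*) may be truncated and can hide
  pathology at the lung base or apex.
* **Image noise.** The standard deviation of Hounsfield units (HU) in a
  homogeneous tissue volume reflects the delivered dose: fewer photons mean
  more quantum noise.

`ldctqa` computes both from a CT volume plus organ segmentation masks
(five lung lobes and the aorta), producing a per-scan JSON/PDF report and
cohort summaries. The neural segmenter that produces the masks is an
external, pluggable component; everything downstream of the masks — the
cleaning, geometry, and noise mathematics — is implemented here and is
verifiable on synthetic phantoms with exact ground truth.

## Coordinate convention

All arrays are held in one canonical orientation: axis 1 increases toward
the patient's left, axis 2 toward posterior (dorsal), axis 3 toward
cranial. Slice 1 is the caudal-most slice. `load_volume()` reorients NIfTI
and DICOM input into this frame using the file's direction metadata; a file
without usable metadata is loaded as-is and flagged
(`ORIENTATION_UNRESOLVED`) rather than guessed at.

The cranio-caudal voxel spacing `dz` is taken from the modal inter-slice
distance of the DICOM slice positions, not from the slice-thickness tag:
distance along z is what converts slice counts into millimetres, and the
thickness tag may disagree with the actual increment (overlapping or gapped
reconstructions). The tag is used only when positions are absent.

## Coverage

The five lobe masks are each reduced to their largest 26-connected
component (discarding stray voxels a segmenter occasionally produces) and
unioned into one lung mask. Then, with `n` slices in total and the lung
occupying slices `first..last`:

* caudal overscan = `(first - 1) * dz` mm, cranial overscan =
  `(n - last) * dz` mm;
* underscan (per direction) is flagged iff the lung touches slice 1 or
  slice `n`; a flagged direction has overscan 0 by construction.

A **zero-margin convention** is used deliberately: no tolerance (such as
the 2 cm margin subtracted in parts of the older literature) is removed
from the measured distance. The measurement stays continuous and maximally
sensitive; *alerting* is a separate, configurable decision
(`flag_exceptions()` with site-specific thresholds), because small
overranges are unavoidable in practice (breathing motion, scout
uncertainty).

A scan whose lung touches the edge slice reports overscan 0 mm *plus* the
underscan flag — the two are kept separate rather than encoding "not
measurable" into the distance.

## Aortic-blood extraction

Noise must be measured in a volume that contains nothing but blood; wall,
valve, or calcification voxels have different attenuation and would inflate
the estimate. Precision is therefore prioritized over recall throughout —
losing lumen voxels is harmless, gaining non-blood voxels is not. Four
steps:

1. **Largest component** of the aorta mask (26-connected).
2. **In-plane erosion to a metric margin** (default 3.0 mm, chosen to clear
   an aortic wall of mean thickness 1.9 mm with headroom). The erosion
   runs slice-by-slice with a 3×3 structuring element for
   `n = ceiling(margin / min(dx, dy))` iterations. A voxel surviving `n`
   such erosions has Chebyshev distance at least `n + 1` voxels from the
   background, hence in-plane Euclidean distance at least
   `(n + 1) * min(dx, dy) > margin` — the Euclidean margin is guaranteed in
   every in-plane direction at the cost of slight over-erosion, which is
   the right side to err on here. Erosion never couples slices along z:
   the vessel runs cranio-caudally, so a 3D erosion would needlessly eat
   the ends.
3. **Arch split.** The ascending aorta and arch sit in the upper slices
   and would over-weight cranial noise; they are removed by deleting the
   minimal number `k` of cranial-most slices such that the remaining 3D
   mask has at least two connected components, then keeping the component
   with the **most posterior centroid** — the descending aorta. Centroids
   are compared over whole components (not single slices) for robustness
   to tortuous vessels, and if more than two components appear, the most
   posterior still wins. A mask that never splits (no arch in the scanned
   range, e.g. a straight descending segment) is passed through unchanged.
4. **Trim to the lung extent.** Lumen voxels are kept only on slices
   within the lung's occupied slice interval, so the abdominal aorta below
   the lung (and anything above the apex) never contributes. Interval
   semantics are used — a connected lung cannot have interior lung-free
   slices, so "slices containing lung tissue" and the interval coincide.

Each step that empties the mask raises an error naming the step; the
per-scan driver records it and reports noise as unavailable rather than
aborting a batch.

## Noise

With the pure blood mask `M` and volume `V`:

$$\mu_{raw} = \mathrm{mean}(V[M]), \qquad
  \sigma_{raw} = \mathrm{sd}(V[M])$$

using the sample (n − 1) standard deviation — at realistic lumen sizes the
difference from the population form is negligible, but it is fixed for
reproducibility. `sigma_raw` depends on voxel size: averaging larger
voxels pools more photons and suppresses noise in proportion to
$1/\sqrt{v}$. It is therefore normalized to a reference voxel volume of
1 mm³:

$$\sigma_{norm} = \sigma_{raw} \sqrt{\frac{v_{raw}}{1\ \mathrm{mm}^3}},
  \qquad v_{raw} = dx \cdot dy \cdot dz$$

`v_raw` always comes from the spacing metadata established at load time,
never from the thickness tag. The invariance is exact for independent
voxel noise: 2×2×1 block averaging quarters `v_raw` relative change and
halves `sigma_raw`, leaving `sigma_norm` unchanged (verified on phantoms
to well under 5%). Noise comparability across reconstruction kernels or
iterative reconstruction is *not* claimed — the metric is comparable
within one reconstruction setting.

A minimum mask size (default 100 voxels) guards against degenerate lumens:
below it, noise is reported as unavailable instead of as an unstable
number.

The exposure side uses `effective mAs = mAs / pitch`; for an ideal
Poisson-limited detector, noise scales as $1/\sqrt{\mathrm{effective\
mAs}}$. The package applies this only as a phantom property (injected
noise levels mapped through the proportionality) and as a metadata
utility; no dose reconstruction is attempted.

## Cohort statistics

`tally_ratings()` reproduces the reader-style tally: counts per 6-point
label (6 = Perfect … 1 = Insufficient) and, per label, the cumulative
proportion of scans rated *at least* that well. Each cumulative proportion
carries an exact binomial confidence interval.

The interval is **Clopper–Pearson**, computed by beta inversion
(`qbeta(alpha/2, k, n-k+1)` and `qbeta(1-alpha/2, k+1, n-k)`); for
`k = n` the lower bound has the closed form $(\alpha/2)^{1/n}$. The choice
is deliberate: with n = 98 and all successes the lower bound is
$(0.025)^{1/98} = 96.3\%$, the value a reader-study table of this kind
prints, whereas Wilson or normal approximations give visibly different
bounds. The implementation is cross-checked in the test suite against a
bisection on explicit binomial tail sums for every `(k, n)` with
`n ≤ 50` to 1e-6.

`summarize_cohort()` reports **conditional** directional overscan
statistics — mean and SD over the scans where that overscan is positive —
so the many exactly-bounded or underscanned scans do not drag directional
means toward zero (a consequence: the mean total overscan is not the sum
of the directional means). Underscan rates are plain proportions; scans
without a noise value are excluded from noise statistics and counted.

## The phantom generator

Every geometric and statistical claim above is tested against synthetic
phantoms with voxel-exact ground truth (`generate_phantom()`):

* two lung tubes subdivided into five planar lobe bands (three right, two
  left), occupying exactly the slices between configurable caudal/cranial
  gap margins, so truth overscan is `gap_slices * dz` *by construction*;
* a candy-cane aorta — ascending limb, half-torus arch above the lung
  apex, descending (posterior) limb extending below the lung — with
  separate lumen and wall compartments (default lumen radius 9 mm, wall
  1.9 mm, the population mean wall thickness);
* a soft-tissue body ellipse, air background, and additive Gaussian noise
  of known standard deviation on top of the noise-free tissue map
  (lung −800, blood 40, wall 50, soft tissue 30 HU).

Defaults use a 96×96×100 grid at 1.25×1.25×1.5 mm — a deliberately small
field of view that keeps the full anatomy topologically faithful (arch
split, wall, sub-lung aorta) while generating in a fraction of a second.
`sample_cohort_specs()`/`generate_cohort()` randomize z-extent, slice
spacing (1–2.5 mm), margins (0–20 slices) and noise (5–40 HU) on a
64×64 in-plane grid, and force an exact fraction of phantoms to touch a
scan edge so cohort underscan rates have a known expected value.

What the phantom does **not** emulate — and hence what passing tests do
not show about clinical data: realistic anatomy (lungs are tubes, lobes
are planar bands), segmentation error (truth masks are perfect; the
package's own largest-component cleaning is exercised with synthetic
satellites instead), spatially correlated CT noise (the generator's noise
is i.i.d. Gaussian, adequate because every quantity measured is a second
moment of a masked voxel set, but a real noise power spectrum would
slightly change the block-averaging arithmetic), beam hardening, motion,
and calcifications. The margin-based purity argument transfers to real
data only insofar as the segmenter's aorta boundary error stays below the
erosion margin — which is exactly why the margin, not an HU filter, is the
mechanism.

Verification sizes used throughout the tests and the acceptance script:
200 random phantoms for coverage exactness, 100 arch-enabled phantoms for
lumen purity and posterior-limb selection, and three phantoms with ≥10⁵
lumen voxels (injected σ of 10, 30, 60 HU) for noise recovery within 2%
and resampling invariance within 5%.

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| `connectivity` | 26 | robust to thin diagonal bridges in organ masks; configurable (6 available) |
| `margin_mm` | 3.0 | clears a 1.9 ± 0.3 mm wall with headroom |
| `min_voxels` | 100 | below this, a noise SD is too unstable to report |
| `hu_floor` | −19000 | HU below this indicate corrupted rescale metadata |
| spacing tolerance | 10% | inter-slice distances deviating more from the mode are flagged |
| review thresholds | 50 mm / 80 HU | starting points only; sites should tune them |

Ties between equal-sized components are broken toward the component
containing the smallest linear voxel index, making `largest_component()`
deterministic. Masks are never resampled: a mask on a different grid than
its volume is an error, because silent interpolation would corrupt both
the coverage boundary slices and the partial-volume behaviour of the noise
mask. JSON is the primary report artifact; the PDF is derived and
optional.

## Limitations

* The neural segmenter is not bundled; the package consumes its masks
  (`backend = "precomputed"`) or phantom truth. Mask *quality* assessment
  is a human task by design — the geometric cleaning here removes small
  artefacts, not systematic segmentation failure.
* Orientation checking is limited to metadata consistency; a volume whose
  content was rotated without updating its metadata is not detectable
  here.
* Noise values are comparable within one reconstruction setting only.
* The method is retrospective: it audits acquisitions after the fact and
  cannot reduce the dose of the scan it measures.
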