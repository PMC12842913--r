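# ldctqa — scan-coverage and image-noise QA for low-dose chest CT

`ldctqa` is an R package for automated, acquisition-level quality
assurance of low-dose CT (LDCT) lung-screening examinations. Given a CT
volume and organ segmentation masks (five lung lobes and the aorta, from
any external segmenter or from files), it quantifies — with no user
interaction per scan:

* **Overscanning** — the scanned z-range beyond the lung parenchyma, as
  `slices beyond the lung × dz` in mm, separately caudal and cranial,
  with a zero-margin convention (no tolerance subtracted);
* **Underscanning** — lung tissue reaching the first or last slice,
  flagged per direction (possible truncation of the lung);
* **Image noise** — the standard deviation of Hounsfield units within an
  automatically extracted *pure descending-aortic-blood* volume,
  normalized to a 1 mm³ voxel:

  σ_norm = σ_raw · √(v_raw / 1 mm³),  v_raw = dx·dy·dz,

  making the value comparable across voxel sizes (within one
  reconstruction kernel). Blood is homogeneous at CT scale, so any HU
  spread inside a pure blood mask is noise, not anatomy.

The blood mask is derived from the aorta segmentation by: largest
connected component → slice-wise binary erosion to a ≥ 3 mm in-plane
margin (clearing the ~1.9 mm vessel wall) → removal of the ascending
aorta by cutting cranial slices until the mask splits and keeping the
posterior (dorsal) component → trimming to the lung's slice interval.

Per-scan results serialize to JSON (and optionally a one-page PDF);
cohort tools aggregate records into conditional overscan statistics,
underscan rates, and reader-style rating tallies with exact
(Clopper–Pearson) binomial confidence intervals. A synthetic chest
phantom generator with voxel-exact ground truth (lungs, lobes, candy-cane
aorta with wall, scan margins, known injected noise) makes every stage
verifiable without clinical data.

Intended users: screening programs and radiology physics/QA teams who
want continuous, objective monitoring of scan range and dose-related
image quality, with exception-based human review.

## Worked example

```r
library(ldctqa)

# a synthetic chest with known geometry and 22 HU injected noise
ph  <- generate_phantom(phantom_spec(noise_sigma = 22, seed = 2026))
seg <- segment(ph$volume, backend = "phantom-truth", truth = ph$truth)

report <- run_scan(ph$volume, masks = seg, scan_id = "demo-phantom")
print(report)
#> <qa_report> demo-phantom (backend: phantom-truth)
#>   coverage: caudal 21.0 mm, cranial 27.0 mm
#>   noise: sigma_norm 33.79 HU over 4624 voxels
flag_exceptions(report)
#> [1] "pass"
```

The phantom was built with 14 empty caudal slices and 18 empty cranial
slices at dz = 1.5 mm, so the measured overscan of 21.0 / 27.0 mm is the
ground truth exactly. The noise stage measured σ_raw ≈ 22 HU (the
injected value) over 4624 blood voxels of 2.34 mm³ each, giving
σ_norm = 22.1·√2.34 ≈ 33.8 HU. `flag_exceptions()` applies the
configured review thresholds (underscan or integrity flags always force
review).

Rating tallies with exact intervals:

```r
tally_ratings(rep(6:1, times = c(16, 73, 8, 1, 0, 0)))
#> <rating_tally> n = 98
#>   Perfect          16   16.3%  [CI: 9.6-25.2%]
#>   Nearly Perfect   73   90.8%  [CI: 83.3-95.7%]
#>   Good              8   99.0%  [CI: 94.4-100.0%]
#>   Acceptable        1  100.0%  [CI: 96.3-100.0%]
#>   Poor              0  100.0%  [CI: 96.3-100.0%]
#>   Insufficient      0  100.0%  [CI: 96.3-100.0%]
```

Real volumes load from NIfTI files or DICOM series directories
(`load_volume()`, with pre-flight `check_integrity()` covering HU
plausibility, slice-spacing consistency, orientation and rescale
metadata); segmentation masks load from NIfTI label files
(`backend = "precomputed"`). A command-line wrapper lives in
`inst/cli/qa.R` with `run`, `cohort` and `phantom` subcommands.

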