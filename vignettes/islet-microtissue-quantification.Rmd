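---
title: "Quantifying beta-cell proliferation in 3D islet microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-cell proliferation in 3D islet microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmt)
```

## The measurement problem

Reaggregated human islet microtissues (MTs) are size-standardized spheroids
of ~1700 primary islet cells (~150 µm diameter, about one islet equivalent).
After compound treatment, a microtissue is stained for DAPI (all nuclei),
NKX6.1 (a nuclear transcription factor marking beta-cell identity), and EdU
(a thymidine analog incorporated during DNA replication, so nuclear EdU marks
cells that divided during the labeling window). Whole-MT confocal Z-stacks are
acquired at a 3 µm axial step. The quantities of interest per microtissue are
counts — total cells, beta cells, proliferating cells, proliferating beta
cells (EdU and NKX6.1 colocalized) — and the derived percentages: beta-cell
fraction (NKX6.1+/DAPI+), total proliferation (EdU+/DAPI+), beta-cell
proliferation (EdU+NKX6.1+/NKX6.1+), and non-beta proliferation
(EdU+NKX6.1−/NKX6.1−), along with mean NKX6.1 intensity and spheroid volume.

The baseline rates are tiny (a control MT has on the order of 2–3
proliferating cells out of ~1400, i.e. ~0.2%), and compound-induced rates top
out around 6%, so the pipeline must count individual rare nuclei correctly in
a dense, anisotropically sampled 3D volume.

## The four-step algorithm

1. **Spheroid detection** (`detect_spheroid`). The DAPI channel is smoothed
   with an edge-normalized Gaussian (default sigma 2 µm), clipped at its 85th
   intensity percentile, and thresholded by Otsu's criterion; the binary
   volume is closed morphologically (5 µm radius, per-axis voxel conversion),
   the largest connected component is kept, and internal holes are filled per
   Z-plane. The percentile clip removes the long nuclear-intensity tail so
   the two Otsu classes are tissue versus background rather than nuclei
   versus everything else; without it the threshold sits far up the edge
   ramp and the mask systematically under-covers the spheroid. A detection
   whose foreground/background mean ratio is below 1.2, or whose volume is
   below `min_spheroid_volume_um3`, raises a "no spheroid detected" error
   rather than returning a noise mask.

2. **Nuclear segmentation** (`segment_nuclei`), restricted to the spheroid
   mask. Dynamic thresholding is implemented as local-mean thresholding: a
   voxel is foreground when it exceeds the mean intensity over a 15 µm
   physical window (computed over in-mask voxels only) by `offset_k` robust
   SDs (MAD) of the in-mask intensities. Touching nuclei are split by a
   marker-controlled watershed: seeds are maxima of the anisotropic Euclidean
   distance transform (per-axis physical spacing), thinned to a minimum
   separation, and grown by priority flooding on the distance transform.
   Labels outside the 30–1500 µm³ volume gates are discarded.

3. **Marker segmentation** (`score_markers`). The NKX6.1 channel is first
   truncated to its (1, 99.5) in-spheroid percentiles (`truncate_intensities`)
   so that stacks with very different staining intensities — NKX6.1 rises
   strongly with treatment — present a similar range to the threshold. The
   same dynamic threshold then classifies marker voxels, and a nucleus is
   called positive when more than half of its voxels are above threshold.
   EdU is scored the same way without truncation. Because the threshold is
   contrast-based, rescaling a truncated channel does not change any call.

4. **Colocalization** (`colocalize_labels`): proliferating beta cells are the
   set intersection of the beta-positive and EdU-positive label sets, and
   `quantify_mt` turns counts into the reported percentages. Zero
   denominators (e.g. beta-cell proliferation in an MT with no detected beta
   cells) produce `NA` with a warning, never an error or a silent zero.

### Parameter choices

Commercial high-content analysis software does not document its "dynamic
thresholding", so the local-mean form and its parameters are this package's
own, chosen and validated against simulated ground truth:

* `window_um = 15` — several nucleus diameters, so the local mean tracks
  regional background without following individual nuclei.
* `offset_k = 2.0` and `smooth_sigma_um = 0.5` — a sweep against ground truth
  showed that heavier smoothing or a lower offset merges Z-adjacent nucleus
  pairs (the 3 µm step plus axial PSF blur is the resolution bottleneck):
  offset 1.0 with 1 µm smoothing mis-merged ~13 of 200 nuclei, offset 2.0
  with 0.5 µm smoothing ~4.
* `seed_min_distance_um = 2.5`, slightly below the mean nucleus radius, so
  nuclei whose distance-transform maxima sit close together still get two
  seeds; the volume gates remove any over-segmented fragments.
* Volume gates 30–1500 µm³ are generous bounds around the ~113 µm³ of a 3 µm
  -radius human nucleus.
* Marker positivity at 50% of nucleus voxels balances PSF-blurred halo voxels
  against partial-volume effects at the 3 µm step.
* `nkx_mean_domain = "beta"`: mean NKX6.1 intensity is averaged over
  beta-classified nuclei. The averaging domain is genuinely ambiguous in the
  field's reporting; a whole-population mean is available via the config
  flag, and the choice is logged in every output.

## The synthetic-data generator

No public imaging data exist for this assay, so the package ships a forward
model that renders what the pipeline assumes and reports ground truth for
every nucleus:

* **Geometry**: nuclei are non-overlapping spheres (lognormal radii, mean
  3 µm, CV 0.15) packed uniformly into a spheroid ball by rejection sampling
  with a spatial hash (10,000 attempts per nucleus, insertion-order
  tie-break). The test-scale default is 200 nuclei in a 40 µm-radius
  spheroid, which keeps a full stack at ~30 x 180 x 180 voxels; the
  physiological scale (1700 nuclei, 75 µm) is a parameter choice away and is
  used nowhere in the test suite, whose problem sizes are chosen so the whole
  suite runs in minutes.
* **Phenotypes**: independent Bernoulli beta identity (default fraction
  0.55, inside the 40–65% range reported for human islets) and proliferation
  (the 4-day EdU window collapsed to one cumulative event; no cell-cycle
  dynamics). Control rates are 5e-4 (beta) and 3.75e-3 (non-beta), i.e. 0.2%
  of all cells, the non-beta rate 7.5x the beta rate — the midpoint of the
  5–10x range observed in donors.
* **Intensities**: DAPI lognormal (CV 0.1) around 1000; NKX6.1 lognormal
  (CV 0.35, a broad distribution standing in for the unreported one) around
  600 for beta nuclei with a 40 a.u. floor elsewhere, and halved in
  proliferating beta cells (NKX6.1 is reduced in EdU+NKX6.1+ cells); EdU 800
  in proliferating nuclei. A diffuse DAPI component at 15% of the nuclear
  amplitude fills the spheroid ball, standing in for cytoplasmic staining and
  out-of-focus light — without it a rendered spheroid is an empty point cloud
  with no object boundary for step 1 to find, unlike any real stack.
* **Optics**: 0.5 µm lateral pixels (typical for a 40x dry objective on a
  benchtop high-content confocal, and configurable), 3 µm Z-step, Gaussian PSF
  (sigma 0.5 µm lateral, 1.5 µm axial), scaled-Poisson shot noise plus
  Gaussian read noise, 16-bit clipping.
* **Dose effects**: proliferation probabilities follow a Hill curve per class
  (EC50 3 µM, Hill 1.5, maxima tuned to ~6% total proliferation at
  saturation); stimulated secretion saturates with its own Hill shape while
  basal secretion rises linearly, so fold-stimulation peaks at an
  intermediate dose; insulin content is depleted with dose. Functional
  endpoints are lognormal around those means with CV 0.15 (reported islet-MT
  endpoint tables give mean and SEM only, so the per-MT dispersion is an
  assumption).

What passing tests on this generator do **not** show: robustness to optical
clearing artifacts, depth-dependent attenuation, spectral bleed-through
beyond a constant floor, irregular nucleus shapes, debris, or cell death —
none of which the forward model emulates. Results on real stacks depend on
those factors; the generator establishes correctness of the algorithmic
chain, not instrument-grade validation.

## Statistics

* **ROUT outlier removal** (`rout_outliers`): ROUT as defined by Motulsky
  and Brown is a nonlinear-regression procedure; applied to one group of
  measurements the
  regression model degenerates to a constant, and the package implements that
  reduction — median center, robust scale from the 68.27th percentile of
  absolute residuals with an n/(n−1) small-sample factor, t-distribution
  p-values on studentized residuals, and flagging from the most extreme
  residual inward while `p < q(n−i+1)/n`. Under clean Gaussian samples
  (n = 12, q = 0.05) the mean flagged fraction calibrates below 5%, and a
  planted 15-SD point is flagged essentially always. It is applied per
  endpoint per dose group; proliferation fractions are never outlier-tested.
* **Dunnett's many-to-one comparisons** (`anova_dunnett`): t statistics
  against the shared control with the pooled within-group variance, adjusted
  through the equicorrelated multivariate t distribution evaluated by
  `mvtnorm::pmvt` under a fixed internal seed (adaptive integration,
  tolerance well under the 1e-3 documented for the adjusted p-values). This
  uses the field's standard integration library rather than a bespoke
  Monte-Carlo sampler; the two-group case reduces to the pooled t-test, which
  the tests verify, and `multcomp::glht` serves as an independent
  cross-check.
* **Student's t** is the pooled-variance test (Welch by flag), and group
  summaries are mean ± SEM with the peak-mean dose annotated, matching the
  reporting conventions of the functional figures.

## Numerical conventions and degenerate inputs

Arrays are `(z, y, x)` with voxel centers at `(i + 0.5) x voxel size`; all
physical parameters are µm and converted per axis. Otsu ties break to the
lowest qualifying threshold. Identical seed and configuration give
bit-identical stacks, label maps, and tables; `with_seed` restores the
caller's RNG state. Constant images, empty masks, empty record lists, zero
denominators, and sub-3-voxel threshold windows each have a defined contract
(error or `NA`/empty result) exercised in the tests.

## Known limitations

* At a 3 µm Z-step, nucleus pairs stacked within ~4–5 µm axially are at the
  sampling limit; the watershed recovers most but not all, so total counts
  run 1–4% low. The acceptance checks bound this bias.
* The NKX6.1 intensity model is a stand-in (lognormal, attenuation factor
  0.5); per-nucleus intensity distributions are not reported for real MTs.
* Per-stack (not per-well or per-plate) NKX6.1 truncation is the default;
  per-plate normalization would require joint processing of all stacks.
* No deconvolution, no learned segmentation, no multi-spheroid support beyond
  largest-component selection.
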