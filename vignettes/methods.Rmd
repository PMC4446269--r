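---
title: "Methods: simulating and quantifying plaque burden in light-sheet volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying plaque burden in light-sheet volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidscope)
```

## Overview

`amyloidscope` implements a cube-based stereological quantification of
β-amyloid plaque burden for cleared-brain light-sheet volumes, together with
a synthetic image generator that provides exact ground truth. The pipeline is
simulate → segment → quantify → compare: planted spheres stand in for
plaques, an image-formation model degrades them the way an ultramicroscope
does, threshold segmentation with 3D connected components recovers objects,
and per-cube summaries (counts per mm³, plaque load, equivalent-diameter
histograms) are compared across age groups with nonparametric tests.

This vignette records the model assumptions, the parameters that matter, the
numerical choices, and what the synthetic test bed does and does not
establish about real data.

## The measurement model

**Equivalent spherical diameter.** Plaques are treated as approximately
spherical; a segmented object of volume $V$ (voxel count × voxel volume) is
summarised by $d = 2\,(3V/4\pi)^{1/3}$. `equivalent_diameter()` is the exact
closed form; it is strictly increasing in $V$, so filtering and binning on
$d$ is equivalent to filtering on volume.

**Counting floor.** Objects with $d < 8$ µm are never counted
(`filter_min_diameter()`, boundary inclusive). The instrument's lateral
resolution is ~2 µm and its axial resolution ~5 µm and both degrade toward
the field edges, so sizes below 8 µm are unreliable; the floor is applied to
the *measured* equivalent diameter, not the bounding box, because the floor
is quoted as a diameter.

**Sample cubes.** Counts and loads are measured inside axis-aligned cubes
whose volume is fixed to 0.1 % of the animal's segmented cortex volume
(`place_sample_cubes()`), the standard normalisation that makes cubes
comparable across animals of different brain sizes. The cube edge is
$(0.001\,V_\mathrm{cortex})^{1/3}$ rounded to whole voxels; the rounding
slack is the only deviation from exact 0.1 %. A plaque belongs to a cube iff
its centroid lies in the half-open box $[\mathrm{origin}, \mathrm{origin} +
\mathrm{edge})$ — half-open faces make the rule unbiased for counts and
prevent double counting by adjacent cubes. Plaque load uses voxel
membership instead, because load is a volume fraction. Cube placement is
seeded-random inside the cortex mask; no anatomical atlas is attempted, since
the reference workflow placed cubes manually in the frontal cortex.

**Shrinkage.** Dehydration/BABB clearing shrinks tissue by roughly 20 %
linearly, biasing measured sizes low. Interpreting the bias as
$\mathrm{measured} = \mathrm{true}\,(1-s)$ with $s = 0.20$,
`correct_shrinkage()` divides by $1-s$ (40 µm → 50 µm at the default). The
correction is **off by default** in pipeline outputs: reported sizes remain
in the measured (cleared-tissue) frame, and the correction is applied only
when explicitly requested, so corrected and uncorrected values are never
mixed silently.

**Group comparison.** The statistical unit for between-group tests is the
animal (each animal's mean over its six cubes), which avoids
pseudo-replication of cubes within animals; per-cube tests are also emitted
but flagged exploratory. Tests are two-sided Mann–Whitney
(`mann_whitney_u()`): $U$ from rank sums with midranks for ties, exact
p-values by full enumeration of all $\binom{n_a+n_b}{n_a}$ labelings when
$n_a+n_b \le 12$ (the regime of 5-animal groups), otherwise a
normal approximation with tie and continuity corrections. Within-group
heterogeneity is assessed with Kruskal–Wallis, which delegates to
`stats::kruskal.test()`. Per-bin size-fraction differences between groups
(`compare_group_fractions()`) test animal-level bin fractions per bin, so
any reading of "which size range differs" is recoverable from the per-bin
table. Significance stars are `***` < 0.001, `**` < 0.01, `*` < 0.05,
boundaries exclusive, on raw p-values: no multiple-testing correction is
applied, matching the reporting convention of the reference workflow; a
supplementary Welch t statistic is reported beside the primary Mann–Whitney
result on plaque load because both appear in the literature this mirrors.

## The synthetic scene generator

The generator emulates what the pipeline must be robust to, not the full
physics of the instrument.

**Plaques.** Diameters are drawn from a `size_dist_spec()`: either empirical
bins (draw a bin by probability, then uniform within — used with the
published adult distribution, `adult_size_distribution()`: 8–10 µm 11.7 %,
10–20 µm 38.7 %, 20–30 µm 27.7 %, 30–40 µm 21.9 %) or a truncated
lognormal. Centres are packed by rejection sampling with a minimum
surface-to-surface separation and full containment in the target region;
larger spheres are placed first, which keeps packings up to ~15 % effective
fill reliable. Rasterization uses strict voxel-centre membership by default:
a voxel is foreground iff its centre lies inside a sphere. This makes the
rasterizer exactly testable against a brute-force enumeration oracle, and
because sphere centres carry uniform sub-voxel jitter, the expected voxel
count equals the true volume — the diameter estimate is unbiased to within
Jensen-level terms (measured: |bias| < 0.01 µm, sd 0.03–0.16 µm at 2 µm
voxels over 8–40 µm). An optional 2× supersampling flag rasterizes
partial-volume boundaries instead.

**Artifacts.** Vessels are persistent random-walk polylines (3–6 segments)
dilated to a 3–8 µm radius and painted at plaque-like intensity — the
quantitative geometry of perfusion artifacts is not documented anywhere, so
a shape that is reliably tube-like (elongation ≫ 1) is what matters.
Stripes are ridges running the full illumination (x) axis with 1–2 voxel
cross-section. Both record every painted voxel in the ground truth, so
exclusion can be verified by set containment. Segmentation flags vessels by
principal-axis elongation (> 5) or absolute length (> 150 µm, comfortably
above the 1.55·r ≈ 54 µm axis length of the largest 70 µm sphere), and
stripes by bounding-box anisotropy (x-extent ≥ 8× both other extents).
These rules automate exclusions that the semi-automatic reference workflow
did under manual control; an explicit exclusion mask is also accepted for
parity with manual workflows.

**Optics.** The light sheet is a Gaussian beam: its thickness follows
$\sigma_z(x) = \sigma_{z0}\sqrt{1 + ((x-x_0)/x_R)^2}$ with Rayleigh range
$x_R = \pi w_0^2/\lambda$ (λ = 0.405 µm, violet diode). The volume is
blurred slab-by-slab along the illumination axis with the local axial sigma
($\sigma_{z0}$ from the 5 µm axial FWHM; FWHM $= 2\sqrt{2\ln 2}\,\sigma$),
plus a constant 2 µm FWHM lateral blur. This reproduces the clinically
relevant artifact — nearby plaques merging along z off-waist — without ray
tracing, refractive-index mismatch or scattering, which are out of scope.
Depth attenuation multiplies intensity by $e^{-\mu\,\mathrm{depth}}$ along
the depth axis. Camera noise is optional Poisson shot noise plus Gaussian
read noise, rounded and clipped to the 12-bit range.

**What passing does not show.** The generator's plaques are perfect spheres
on a uniform background; real plaques have halos, cores and irregular
borders, the background has autofluorescence texture, and real attenuation
is spatially heterogeneous. Recovery results here validate the *pipeline
arithmetic* (labeling, measurement, cube accounting, statistics) and the
*direction* of optical artifacts, not segmentation accuracy on real tissue,
where threshold choice dominates.

## Numerical choices

- **Voxel size** defaults to 2 µm isotropic (the instrument's lateral
  resolution bound), keeping sphere rasterization accurate at the 8 µm
  floor; anisotropic sizes are supported per axis. Axis convention:
  z = optical-section axis (TIFF page), y = depth-from-surface
  (attenuation), x = illumination (blur growth); recorded as `"zyx"` in the
  sidecar.
- **Threshold.** Per-volume fixed threshold is the default mode (the
  reference workflow used a manual threshold per volume; its values are
  unpublished, so no fidelity is claimed). Otsu mode maximizes between-class
  variance on the integer histogram; across the empty-histogram gap of a
  well-separated bimodal image the criterion is flat, and the plateau
  midpoint is returned so the threshold sits centrally between the classes.
  A constant image is a degenerate-input error. Ties at the threshold count
  as foreground (documented; affects voxel counts only at the margin).
- **Connectivity** defaults to 26 (most permissive, matching the particle
  behaviour of 3D rendering software); 6 and 18 are exposed and tested.
- **Histogram bins** start at the 8 µm floor (so the first bin matches the
  published "8–10" row) and continue in 10 µm groups, half-open
  $[e_i, e_{i+1})$. Empty inputs report zero counts with an `empty` flag
  rather than NaN percentages.
- **Degenerate inputs** raise typed errors naming the problem: packing and
  cube-placement failures report the achieved count; missing voxel-size
  metadata names the expected sidecar; unknown CSV columns are schema
  errors; V ≤ 0, s ≥ 1, empty samples and empty masks are domain errors.
- **Seeding.** Every stochastic stage takes an explicit seed; cohort
  generation derives per-animal, per-stage seeds from one master seed via a
  fixed affine map mod 2³¹−19, so one integer reproduces a cohort
  bit-identically while stages stay independently perturbable.

## Validation scenarios and problem sizes

Three scenario builders wrap the pipeline for validation:

- `recover_planted_totals()` plants **exact group totals** (e.g. the
  published 4411 young / 17829 adult cube totals) only inside a pre-declared
  3×2 cube layout (120-voxel cubes, 8-voxel margins), so pipeline counts are
  comparable to planted totals without edge ambiguity. The scenario images
  at 4 µm voxels with 10–40 µm plaques, ≥ 10 µm separations, read noise of
  20 counts, no attenuation, and a weakly focused sheet (w₀ = 30 µm,
  x_R ≈ 7 mm, so the whole field is near-waist). Closed-form margins — the
  threshold at background + 25 % of amplitude sits 36 read-noise sigmas
  above background; the blurred mid-gap intensity between two spheres 10 µm
  apart is ~2 % of amplitude; the smallest measured diameter (~10 µm) is
  well above the 8 µm floor — make recovery exact rather than approximate,
  which is the point: any lost or merged object is a pipeline defect, not
  noise. The full two-group run takes ~3 minutes on one CPU.
- `measure_size_distribution()` recovers binned size fractions for 5000
  plaques drawn from the adult distribution, rasterized at 2 µm without
  blur or noise across 5 animals. Recovered fractions land within ~1 pp of
  the sampling distribution; the residual deficit in the 8–10 µm bin is the
  expected one-sided loss at the counting floor (a plaque of true d ≈ 8.1 µm
  can measure fractionally below 8 and be dropped, while nothing enters from
  below because nothing below 8 is planted).
- `measure_offwaist_merging()` images one scene of sphere pairs (6 µm gaps
  along z) twice — waist on-scene versus 3 Rayleigh ranges off — and
  reports the fraction of segmented objects above 50 µm. With default
  optics the pairs are separated at the waist and merged off-waist; only the
  direction of the effect is asserted, since its magnitude depends on the
  (unknown) true spatial distribution of plaques in the field.

Where the source workflow reports no value at all — plaque number density
per mm³ for either age group — the generator takes it as an explicit config
field (`cohort_group(density_per_mm3 = ...)`; the demo uses 2500/7000 mm⁻³
to give usefully populated cubes on small grids) and no fidelity to real
densities is claimed.

## Known limitations

- Merged plaques are measured, not repaired: no watershed splitting, by
  design — the merging artifact is itself a quantity of interest.
- Intensity-mode cortex segmentation (Otsu + largest component + closing)
  suits clean synthetic overviews; real overview stacks would need
  bias-field handling.
- One threshold per volume; no adaptive/local thresholding, although depth
  attenuation in real data is the main argument for one.
- TIFF + JSON sidecar and CSV are the only formats; no proprietary
  microscope formats, HDF5 or OME-Zarr.
- Hemisphere handling is a tag; no midline detection or registration
  between animals.
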