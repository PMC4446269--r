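# amyloidscope

Quantification of β-amyloid plaque burden in cleared-brain light-sheet
(ultramicroscopy) volumes, with a fully synthetic, ground-truthed test bed.

## The problem

Light-sheet microscopy of chemically cleared APPPS1 mouse brains images every
methoxy-X04-labelled β-amyloid plaque in the intact brain: bright
quasi-spherical deposits on a dark parenchyma, recorded as a stack of optical
sections on a 12-bit camera. Turning such volumes into biology means:

- **counting** plaques per mm³ inside sample cubes whose volume is fixed to
  0.1 % of each animal's segmented cortex volume (so the sampling unit is
  normalised across animals),
- measuring the **plaque load** — plaque volume as a percent of cube volume,
- and summarising **sizes** via the equivalent spherical diameter
  *d* = 2 · (3*V* / 4π)^⅓, binned into 10 µm size groups above an 8 µm
  counting floor (below which the instrument cannot resolve reliably),

while excluding blood-vessel artifacts (incomplete perfusion leaves bright
tubes) and the fine stripes that light-sheet illumination produces, and while
being honest about two known biases: tissue clearing shrinks plaques by about
20 % (linear), and away from the sheet waist the Gaussian beam thickens with
its Rayleigh range *x*_R = π·w₀²/λ, merging nearby plaques along the optical
axis into spuriously large objects.

Because the original specimens are not available, the package pairs the
measurement pipeline with a seeded synthetic-volume generator that plants
spheres with known positions and diameters, adds vessels, stripes,
Rayleigh-range axial blur, depth attenuation and camera noise, and emits
exact ground truth — so every stage of the pipeline is testable against
planted truth.

## What is in the package

| Area | Functions |
| --- | --- |
| Synthetic volumes | `sample_diameters()`, `place_plaques()`, `rasterize_plaques()`, `add_vessels()`, `add_stripes()`, `apply_lightsheet_blur()`, `apply_attenuation()`, `add_noise_and_quantize()`, `generate_cohort()` |
| IO | `read_volume()` / `write_volume()` (multi-page TIFF + JSON sidecar), `read_table()` / `write_table()` (typed CSV), `load_config()` (YAML/JSON) |
| Segmentation | `compute_threshold()` (fixed/Otsu), `binarize()`, `label_components()` (3D, 6/18/26-connectivity), `component_table()`, `classify_artifacts()`, `filter_min_diameter()`, `segment_plaques()` |
| Quantification | `equivalent_diameter()`, `segment_cortex()`, `place_sample_cubes()`, `cube_count_density()`, `cube_plaque_load()`, `size_histogram()`, `correct_shrinkage()`, `compare_group_fractions()` |
| Statistics & pipeline | `mann_whitney_u()` (exact by enumeration for small n), `kruskal_wallis()`, `significance_stars()`, `run_pipeline()`, `recover_planted_totals()`, `measure_size_distribution()`, `measure_offwaist_merging()` |

Tables are tibbles throughout and compose with the pipe; fitted test objects
have `tidy()`/`glance()` methods and result types have `autoplot()`/`plot_*()`
helpers. A thin CLI lives at `inst/cli/amyloidscope.R`
(`simulate | segment | quantify | all`).

## Worked example

Simulate one adult-like field, image it through the light-sheet model,
segment, and bin the recovered sizes:

```r
library(amyloidscope)

sim <- simulation_config(grid_shape = c(120, 100, 100), voxel_size_um = 2,
                         noise_gaussian_sd = 15, sheet_waist_halfwidth_w0_um = 30)
d   <- sample_diameters(adult_size_distribution(), 120, seed = 1)
plq <- place_plaques(array(TRUE, c(120, 100, 100)), d,
                     min_separation_um = 5, seed = 2, voxel_size_um = 2)
img <- image_scene(rasterize_plaques(plq, sim), sim, seed = 3)
img
#> <voxel_grid> 120 x 100 x 100 voxels (z,y,x), voxel 2 x 2 x 2 um, 12-bit
#>   physical extent 240.0 x 200.0 x 200.0 um, intensity range [28, 3062]

seg <- segment_plaques(img, segmentation_params(fixed_threshold = 1550))
seg
#> <plaque_seg> 120 objects (120 retained) at threshold 1550

size_histogram(tidy(seg)$equivalent_diameter_um[tidy(seg)$retained])
#>      bin bin_lo_um bin_hi_um count rel_percent
#> 1   8-10         8        10    11    9.166667
#> 2  10-20        10        20    44   36.666667
#> 3  20-30        20        30    36   30.000000
#> 4  30-40        30        40    29   24.166667
#> 5  40-50        40        50     0    0.000000
#> 6 50-Inf        50       Inf     0    0.000000
```

All 120 planted plaques are recovered; the binned percentages track the
sampling distribution (11.7 / 38.7 / 27.7 / 21.9 % in expectation) up to
binomial noise at n = 120. `run_pipeline(demo_config(), seed = 1)` runs the
whole simulate → segment → quantify → stats chain and returns a report with
per-cube counts, densities, loads, histograms and group tests.

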