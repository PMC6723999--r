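# airspacer

Quantification of lung micromechanics on high-resolution tomographic slices
during decremental-PEEP maneuvers.

## The problem

During mechanical ventilation, how does an injured (ARDS) lung deflate at
the scale of its terminal airspaces? Two classical mechanisms compete:

- **derecruitment** — whole airspaces close while the survivors keep their
  size (the behavior reported for healthy lungs);
- **balloon-like shrinkage** — airspaces stay open but shrink in proportion
  to the applied pressure.

Phase-contrast synchrotron CT can image the lung in vivo at ~48 µm
resolution, making the distinction measurable. On every slice, *airspaces*
are operationally defined as gas-density regions bounded by tissue-density
septa. Two metrics summarize each slice and concentric region of interest
(ROI):

- **NAs** — the number of airspaces, counted as local negative-intensity
  peaks of a multi-scale black top-hat enhanced image;
- **ASnum = NAs / analyzed volume** (units/mm³) — airspace density;
- **ASdim = gas area / NAs** (voxels) — mean airspace surface extension.

Regressing ASdim and ASnum on the applied PEEP (OLS over pooled per-slice
observations; extra-sum-of-squares F-tests between regressions; Wilcoxon
signed-rank comparisons with Bonferroni control) reveals which deflation
mechanism dominates: a significant ASdim slope with flat ASnum in the single
ROIs is the balloon (ARDS) signature; the inverse pattern is the
derecruitment (healthy) signature.

`airspacer` implements the full chain for users with stacks of this kind —
plus a seeded synthetic phantom generator with voxel-level ground truth, so
every stage is testable without synchrotron beam time:

| stage | functions |
|---|---|
| phantom generation | `phantom_spec()`, `generate_parenchyma_truth()`, `apply_deflation()`, `render_image()`, `make_peep_series()` |
| segmentation | `exclude_nonventilated()`, `tophat_enhance()`, `count_airspaces()`, `delineate_airspaces()` |
| ROI banding | `pleural_distance_map()`, `partition_rois()` |
| metrics | `roi_volume()`, `compute_metrics()`, `pool_slices()` |
| statistics | `fit_peep_regression()`, `compare_regressions_ftest()`, `wilcoxon_signed_rank()`, `bonferroni()` |
| orchestration | `segment_stack()`, `run_study()`, `simulate_experiment()` |

## Worked example

A noiseless phantom with 25 airspaces per slice, segmented end to end:

```r
library(airspacer)

spec  <- phantom_spec(domain_radius = 1.6, target_count = 25,
                      mean_airspace_diameter = 215, septal_thickness = 96,
                      n_slices = 3, seed = 7)
truth <- generate_parenchyma_truth(spec)
image <- render_image(truth)
seg   <- segment_stack(image, phantom_mask(truth),
                       tissue_threshold = 32500,
                       config = study_config(n_slices = 3))

seg$labels$nas_per_slice
#> [1] 25 25 25
truth_open_counts(truth)
#> [1] 25 25 25
```

A full synthetic decremental-PEEP experiment under balloon-like deflation
(five pressure levels, the fraction of size lost growing from 0 to 40%):

```r
spec <- phantom_spec(domain_radius = 5, target_count = 400,
                     mean_airspace_diameter = 195, septal_thickness = 100,
                     noise_sigma = 2500, fringe_amplitude = 3000,
                     n_slices = 12, seed = 42)
res <- simulate_experiment(spec, "balloon", fractions = c(0, .1, .2, .3, .4),
                           config = study_config(n_slices = 12),
                           level_scatter = 0.8)
res$regression_table
#>   response roi        m      k r_squared p_value  n significant
#> 1    ASdim ALL  0.34657   9.34  0.144578 0.00273 60        TRUE
#> 2    ASdim SUB  0.34638   9.42  0.136269 0.00370 60        TRUE
#> 3    ASdim MAN  0.34581   9.18  0.158182 0.00165 60        TRUE
#> 4    ASdim COR  0.35995   9.41  0.138647 0.00339 60        TRUE
#> 5    ASnum ALL  0.00076 106.70  0.007822 0.50159 60       FALSE
#> 6    ASnum SUB  0.01986 104.14  0.010342 0.43943 60       FALSE
#> 7    ASnum MAN -0.03447 111.66  0.008022 0.49616 60       FALSE
#> 8    ASnum COR -0.02018 107.64  0.000199 0.91482 60       FALSE
```

ASdim falls significantly with PEEP in the whole slice and in every
concentric band (slope ~0.35 voxels per cmH₂O) while ASnum stays flat —
the balloon signature. Running the same experiment with
`mechanism = "derecruitment"` inverts the pattern. `res$truth_comparison`
reports the recovery of the generator's ground truth per pressure level.

Real stacks enter the same way: `read_stack_tiff()` / `read_mask_tiff()`
for multi-page TIFF stacks and masks, then `run_study()` over the
(animal, PEEP) cases. A minimal command-line wrapper for the phantom
workflows is installed at `inst/cli/airspacer`.

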