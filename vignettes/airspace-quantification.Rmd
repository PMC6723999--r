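---
title: "Quantifying airspace micromechanics on tomographic lung slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airspace micromechanics on tomographic lung slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airspacer)
```

## The measurement model

`airspacer` quantifies terminal-airspace number and size on grayscale
tomographic lung slices (isotropic in-plane voxels, default 47.7 µm; a stack
of 40 contiguous slices spans a 1.908 mm slab). An *airspace* is an
operational unit: a gas-density image region bounded by tissue-density
septal structures. It is not claimed to be one anatomical alveolus — at
~48 µm resolution a 110 µm alveolus covers barely two voxels, and
neighbouring alveoli whose septa fall below the resolution limit merge into
one measured airspace.

The per-slice, per-ROI metrics are

* `NAs` — number of airspaces (count of negative-intensity peaks),
* `ASnum = NAs / analyzed volume` in units/mm³, where the analyzed volume
  is the voxel count of the analyzed parenchyma in that ROI times the cubic
  voxel volume,
* `ASdim = gas area / NAs` in voxels (in-plane pixel count), undefined
  (missing) where `NAs = 0`.

`ASdim * NAs = gas_area` holds exactly by construction, and because an
airspace is *counted* in the band holding its peak while its *area*
contributes to every band it overlaps, `NAs` is additive across bands and
gas area is conserved.

### Segmentation: multi-scale black top-hat + h-maxima

Gas is dark on a bright tissue background. The black top-hat — morphological
closing with a disc minus the image — converts dark structures up to the
structuring-element diameter into positive peaks; taking the voxel-wise
maximum over an ascending ladder of disc radii (default 2, 3, 4, 6 voxels,
i.e. element diameters of roughly 190–570 µm) enhances airspaces across the
physiological size range. Pure density thresholds cannot delineate airspace
boundaries at this resolution; the top-hat residue encodes the morphological
criterion (enclosure by septa) jointly with the density criterion.

Counting uses the h-maxima transform: grayscale reconstruction by dilation
of `enhanced - h_depth` under `enhanced`, whose regional maxima are exactly
the peaks with prominence at least `h_depth`. Reconstruction is implemented
in C++ (the standard hybrid raster + FIFO algorithm), since no installed R
package provides grayscale reconstruction. Working with strict local maxima
instead would explode under noise; prominence is the robust notion.

Delineation grows each counted peak over gas-density voxels
(`< tissue_threshold`) with intensity-guided seeded propagation, so
contested voxels resolve at tissue-density ridges, i.e. the septal walls.

### Concentric ROIs

The analyzed parenchyma is partitioned by per-slice 2D Euclidean distance
from the pleural surface into subpleural `[0, 2)` mm, mantellar `[2, 4)` mm
and core `[4, ∞)` mm bands (half-open, so every analyzed voxel has exactly
one band). The three offsets are read as band *inner edges*: the three named
regions tile the section. Excluded non-ventilated regions count as interior
when the outline is formed, so a flooded cap does not masquerade as pleural
surface. The distance convention is voxel-centre to voxel-centre: a voxel on
the outline boundary is one voxel side from the exterior, never zero. The
core band is uncapped; whether the original analysis capped it is not
determinable, and an uncapped band keeps the partition exhaustive.

### Statistics

Each metric is regressed on the applied PEEP by ordinary least squares over
the pooled per-slice observations (no per-animal random effects; a grouping
column is kept so users can stratify). The regressor defaults to the
*measured* PEEP of each nominal level (12.4, 9.6, 6.8, 4.1, 1.1 cmH₂O for
the nominal 12/9/6/3/0 ladder): refitting the published subpleural ASdim
group means reproduces the published slope under the measured-PEEP reading
and not under the nominal one. Regression pairs are compared by the
extra-sum-of-squares F-test (common slope+intercept vs separate fits,
`df = (2, n - 4)`), applied to regressions that are individually significant
at α = 0.05. Paired contrasts use the Wilcoxon signed-rank test — exact by
full sign-flip enumeration up to n = 15 (ties handled through midranks),
normal approximation with tie and continuity correction above. Families of
comparisons are Bonferroni-corrected with decision rule `p ≤ α/m`.

## The phantom generator

Because no real acquisition ships with the package, the phantom module
generates the study conditions with voxel-level ground truth:

* a disc of parenchyma (default radius 5 mm, so all three bands are
  populated) tessellated into `target_count` gas regions separated by septa
  of at least `septal_thickness` (default 100 µm ≈ 2 voxels);
* seeds on a jittered hexagonal lattice whose spacing is tuned so the site
  count barely exceeds the target — surplus sites are removed where the
  lattice is most crowded, so no deep tissue vacancy opens. Each airspace
  takes the `round(π(d/2)²)` pixels nearest its seed among the pixels it
  owns (strictly nearest-seed with a half-septum margin to the bisector):
  per-airspace areas are controlled exactly, and septa arise as thickened
  region boundaries;
* per-airspace diameters are lognormal around the slice mean
  (`diameter_cv`, default 0.2) and each slice carries a lognormal global
  size factor (`slice_size_cv`, default 0.08), giving the pooled per-slice
  metrics a baseline coefficient of variation of about 0.16 — the scale of
  the published full-inflation scatter;
* slices are generated independently (the analysis chain is strictly 2D
  per slice, matching the per-slice pooling of the study design);
* an optional single peripheral cap of flooded/atelectatic tissue
  (`flooded_fraction` of the parenchyma, placed by thresholding the
  projection on a random direction). The original description gives no
  quantitative geometry for flooded regions; one peripheral cap is the
  plausible minimal reading, and its size is exact by construction;
* rendering draws gas at 20000 and tissue at 45000 (16-bit units, leaving
  headroom), adds a one-voxel dark/bright overshoot pair of amplitude
  `fringe_amplitude` at every gas–tissue boundary (the phase-contrast
  signature), then seeded Gaussian noise, then quantizes to 16 bit with a
  clip counter.

Deflation mechanisms follow the two classical modes the study contrasts:
`"balloon"` trims each region's outermost pixels so its area scales by
`1 - fraction` exactly; `"derecruitment"` closes a seeded random
`round(fraction × N)` subset per slice, survivors untouched; `"mixed"`
splits the fraction 50/50. Closure order and pixel-trim order are frozen at
generation, so applying a non-decreasing fraction schedule to the same base
truth yields physically nested states — the synthetic twin of a decremental
maneuver. The fraction-to-pressure mapping is the caller's table; no
pressure–volume model is implied. The remaining two classical mechanisms
(shape change, crumpling) are reserved enum names, not implemented.

`make_peep_series(level_scatter =)` perturbs the per-slice fraction with sd
`level_scatter × fraction`, reproducing the growing between-slice scatter at
low pressure characteristic of the injured lung. The simulated ARDS-like
(balloon) series uses `level_scatter = 0.8`, which takes the ASdim
coefficient of variation from ~0.17 at full inflation to ~0.5 at zero PEEP —
the published pattern; the healthy-like (derecruitment) series uses 0.25,
since the injured-lung scatter is described as large *relative to healthy
conditions*.

### What the phantom does not emulate

Real reconstructed stacks have correlated (streak/ring) noise, anisotropic
blur, heart and vessel structures, 3D airspace continuity between slices,
and gravity-dependent gradients; the phantom has none of these. Passing the
recovery tests therefore demonstrates the correctness of the measurement
chain under controlled conditions — not segmentation performance on
arbitrary real acquisitions, where the enhancement parameters may need
retuning.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `voxel_side` | 47.7 | µm | acquisition geometry; converts counts to volumes |
| `n_slices` | 40 | – | slab of 1.908 mm at the default voxel |
| `radii` | 2, 3, 4, 6 | voxels | top-hat disc ladder; the exact ladder used originally is not published — these bracket the airspace scale and are fully exposed |
| `smooth_sigma` | 0.8 | voxels | Gaussian pre-smoothing; stabilizes peaks under noise, negligible at the airspace scale |
| `h_depth` | 5% of enhanced dynamic range (≥ 1) | gray units | peak prominence threshold; no published value exists |
| `min_separation` | 110 | µm | peak merge radius at the alveolar scale |
| `tissue_threshold` | midpoint of gas/tissue | gray units | density boundary for delineation and exclusion |
| `deep_radius` | 20 | voxels | tissue depth that flags solid non-aerated regions (~1 mm: injury-scale flooding, not septa or transient closures) |
| `min_region` | 50 | voxels | smallest excluded region |
| `offsets` | 0, 2, 4 | mm | ROI band inner edges |
| `alpha` | 0.05 | – | significance level |

## Numerical choices and degenerate inputs

* Enhanced images are rounded to integer grayscale before peak analysis, so
  regional-maximum detection by reconstruction with unit step is exact.
* Plateau peaks count once, at the centroid snapped to the nearest plateau
  pixel; merged peaks keep the highest value with ties broken by lowest
  `(row, col)`; all orderings are lexicographic, making every stage
  deterministic.
* Peaks at tissue density in the raw image are discarded (a negative
  intensity peak is by definition gas-dark); peaks landing on
  above-threshold voxels at delineation are dropped and counted.
* Values outside the mask are left in place during enhancement: the
  pleural/chest-wall neighbourhood legitimately bounds subpleural
  airspaces, and replacing it with a synthetic fill manufactures spurious
  boundary valleys.
* A slice with no detected airspace yields a valid record (`NAs = 0`,
  `ASdim` missing); an empty ROI yields volume 0 and missing `ASnum`; an
  all-zero difference vector gives Wilcoxon `p = 1` with a degeneracy flag;
  a constant response makes the slope test degenerate (`p = NaN`) without
  failing.
* The flooded-region exclusion identifies *deep* dense tissue (≥
  `deep_radius` from any gas voxel), recovers each core's shallow rim by
  geodesic dilation, fills only holes of up to `max_hole` voxels (noise
  speckles — an enclosed open airspace is never swallowed), and excludes a
  region only when its deep core touches the parenchyma perimeter: flooded
  caps are deepest at the pleural surface, while packing irregularities of
  the septal network are deep only in the interior.
* With the exclusion active, heavy derecruitment can shrink the ASnum
  denominator together with the count (closed airspaces *are* non-aerated
  tissue), so the sign of an ASnum trend depends on how much closed tissue
  is excluded; the pure count/size constructions are tested with the
  exclusion disabled.

## Problem sizes used by the tests and the acceptance script

Unit tests run on phantoms of 1.6–2 mm radius with 25–80 airspaces and 1–6
slices. The mechanism-contrast experiments use the study-scale
configuration: 5 mm discs, 400 airspaces per slice at 195 µm mean diameter
(`ASdim` ≈ 13 voxels at full inflation, the published magnitude), 40 slices,
five levels, noise at 10% of the gas–tissue contrast and 3000-unit fringes —
about two minutes per mechanism on one core, chosen as the smallest
configuration that populates all three concentric bands at study-like
airspace sizes. The slope-test size check uses 1000 null replicates of 40
observations.

## Known limitations

* Analysis is strictly 2D per slice; airspaces spanning slices are counted
  once per slice, which matches the original per-slice pooling but is not a
  3D census.
* Plain OLS over pooled slices ignores within-animal correlation — as in
  the original analysis — so p-values are anti-conservative for clustered
  data; the per-animal column enables mixed-model reanalysis outside the
  package.
* ASnum uses the per-slice analyzed volume; whether the original used
  per-slice or per-stack volume is not determinable from the text, and the
  choice is exposed.
* The exclusion step is a heuristic for injury-scale flooding; lungs with
  unusual geometry (caps thinner than `deep_radius`, interior flooding)
  need the thresholds adjusted.
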