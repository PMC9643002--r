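# hippotrack

Quantitative fibre tracking of the hippocampus, as a desk-scale R
package.

Standard anatomically constrained tractography (ACT) terminates
streamlines at the grey-matter/white-matter interface (gmwmi). For the
hippocampus this hides exactly the information of interest: white
matter innervates the hippocampus through its inferior aspect, so
tracks stop at the interface just below it and never show *where
inside* the structure they would naturally end. hippotrack implements a
tailored pipeline for this problem:

1. **m5TT amendment** — remove the portion of the gmwmi immediately
   inferior to a hippocampus mask (re-label it white matter) and assign
   the hippocampus itself to the fifth tissue type, where no anatomical
   priors apply, so streamlines can enter and move within it
   (`amend_to_m5tt()`).
2. **Probabilistic ACT tracking** on spherical-harmonic
   fibre-orientation-distribution (FOD) fields, with FOD cutoff 0.06,
   track lengths 5–300 mm, backtracking, and WM-proportional or
   mask seeding (`generate_tractogram()`).
3. **SIFT2-style weighting** — per-streamline weights `w ≥ 0` fitted so
   that weighted streamline density matches FOD-derived fibre density,
   `min Σ_v (Σ_s w_s L[v,s] − μ D[v])² + λ S̄ Σ_s log²w_s`; connectivity
   is then a *sum of weights*, not a count of tracks (`fit_weights()`).
4. **Long-axis connectomics** — extract streamlines with a hippocampal
   endpoint, split the hippocampus into head/body/tail along a
   normalised long-axis field, and accumulate weight sums per cortical
   parcel with percent-of-connections columns
   (`build_connectivity_table()`, `percent_columns()`).
5. **Endpoint density maps (EDMs)** — super-resolved (default 5×,
   0.2 mm) maps of where streamline endpoints fall inside the
   hippocampus, with group averaging and display windowing
   (`endpoint_density_map()`).
6. **Long-axis statistics** — per-parcel paired t tests (head–body,
   body–tail, head–tail), Bonferroni-corrected at 0.05/3, and a
   four-way classifier of long-axis patterns: anterior-to-posterior
   gradient, posterior bias, anterior bias, body bias (`axis_stats()`).

Real diffusion data are not required anywhere: a synthetic phantom
generator (`build_phantom()`) produces brain-like tissue maps, a curved
hippocampus with a defined long axis, an obstructing grey-matter sheet
inferior to it, and fibre bundles with known densities joining labelled
cortical parcels to known hippocampal segments — so every stage is
testable against ground truth.

## Worked example

```r
library(hippotrack)

phantom <- build_phantom(phantom_config())
phantom
#> hippo_phantom: 40x40x32 voxels, 3 bundle(s), 605 hippocampus voxels

res <- run_pipeline(phantom, n_whole = 8000, n_hippo = 2000, seed = 1)
res$table[, c("name", "whole", "head", "body", "tail", "percent_all")]
#>      name whole head body tail percent_all
#> 1 L_HEADM  2403 2403    0    0       45.02
#> 2 L_BODYL  1901    0 1901    0       35.61
#> 3 L_TAILM  1034    0    0 1034       19.37
attr(res$table, "intra_hippocampal")
#> [1] 411.3
res$edms[["L_HEADM"]]
#> endpoint_density_map: 200x200x160 voxels, 904 endpoints
```

Reading the table: each row is a cortical parcel of the phantom; the
`whole` column is the summed SIFT2-style weight of streamlines joining
that parcel to the hippocampus, and it decomposes exactly into the
`head`/`body`/`tail` columns by where the hippocampal endpoint falls
along the long axis. Here each bundle targets a single segment, so each
parcel's weight lands in one region column, and the ordering of `whole`
values follows the bundles' ground-truth fibre densities (2 : 1.5 : 1).
The EDM is the 0.2 mm map of the 904 hippocampal endpoints associated
with parcel `L_HEADM`; in the default phantom ≥ 80% (here 100%) of each
parcel's endpoint mass falls in its bundle's true target segment.

A thin command-line front end is installed as `exec/hippotrack`
(subcommands `phantom`, `track`, `sift2`, `extract-hippo`, `connectome`,
`edm`, `axis-stats`, `run-all`; global flags `--config`, `--seed`,
`--output-dir`).

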