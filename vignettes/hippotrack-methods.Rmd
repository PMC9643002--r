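---
title: "Quantitative hippocampal tractography with hippotrack: models, parameters and design choices"
author: "hippotrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative hippocampal tractography with hippotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Streamline tractography ordinarily terminates fibre tracks at the
grey-matter/white-matter interface (gmwmi). For most cortex that is the
right behaviour, but for the hippocampus it is exactly wrong: the white
matter that innervates the hippocampus enters through its inferior
aspect (and the fimbria/fornix), so a track that stops at the interface
just below the hippocampus never reveals *where inside* the structure it
would naturally terminate. hippotrack implements a tailored pipeline
that (i) removes the portion of the gmwmi immediately inferior to a
hippocampus mask and re-labels the hippocampus itself as a
"no-priors" tissue so that anatomically constrained streamlines can
enter and move within it, (ii) assigns each streamline a SIFT2-style
weight so that connectivity is a sum of weights rather than a count of
tracks, (iii) aggregates weights into cortical-parcel ×
whole/head/body/tail connectivity tables, and (iv) maps the spatial
density of streamline endpoints inside the hippocampus on a
super-resolved grid (endpoint density maps, EDMs).

Because real diffusion acquisitions and expert manual segmentations are
not reproducible inputs, the package ships a synthetic phantom generator
with known ground truth; every stage of the pipeline is exercised end to
end against that truth.

# Coordinate conventions

All world coordinates are millimetres. Voxel indices are 0-based; the
affine maps a voxel index to the world position of that voxel's
*centre*; a point is contained in voxel `floor(index + 0.5)`. These
conventions hold everywhere: seeding, interpolation, endpoint binning,
`.tck` I/O and NIfTI I/O.

# The five-tissue-type model and ACT rules

A `tissue5tt` volume stores partial volumes for cortical GM, subcortical
GM, WM, CSF and a fifth "pathological / no-priors" tissue (the MRtrix
5TT channel order). The tracking state machine classifies each point by
trilinear interpolation of all five channels:

* channel sum ≤ 0.5 → `OUTSIDE`;
* otherwise the argmax channel, with the deterministic tie-break
  precedence WM > cortical GM > subcortical GM > no-priors > CSF.

The precedence among WM/GM/CSF favours propagation (a point exactly on
a WM/GM boundary continues rather than terminating); placing the fifth
tissue above CSF is our choice and again favours propagation, which is
the fifth tissue's purpose. Rules applied at each new step position:

* `CSF` — rejection event (backtracking may rescue the arm);
* `CORTICAL_GM` / `SUBCORTICAL_GM` — terminate, accept the endpoint;
* `NO_PRIORS` — no constraint; propagation continues while the FOD
  supports it, and a propagation failure here is an accepted ending;
* `OUTSIDE` — terminate; the streamline is accepted only if its other
  endpoint terminated acceptably;
* propagation failure inside WM — rejection event.

## The m5TT amendment

`amend_to_m5tt()` performs the pipeline's key anatomical edit. The
hippocampus mask is translated 1..`depth` voxels (default 2) along the
configured inferior axis; within that band, voxels on the gmwmi or with
combined GM ≥ 0.5 are re-labelled pure WM (this deletes the interface
immediately inferior to the hippocampus), and the hippocampus itself is
re-labelled pure fifth tissue. The operation is idempotent and leaves
every other voxel untouched. On real data the band construction is a
reproducible surrogate for a manually drawn extended mask; `depth`
trades off how much of an imperfectly aligned interface is captured.

# The FOD model

Fibre orientation distributions are real, even-order, antipodally
symmetric spherical harmonics in the MRtrix coefficient ordering
(default `lmax = 8`, 45 coefficients). The phantom synthesizes FODs from
Watson-like lobes `density · exp(kappa ((d·u)^2 − 1))` (default
`kappa = 20`, about a 15° half-width) by least squares on a 500-point
spherical Fibonacci sampling. Sharp lobes truncated at finite order ring
below zero; when the synthesized amplitude dips under −1% of its
maximum, the smallest Laplace–Beltrami band taper `exp(−s l(l+1))`
restoring that bound is applied (found by bisection). The taper is
scale-free, so coefficients remain exactly linear in lobe density — in
particular the l = 0 term, which downstream code uses as the fibre
density, is never touched by it.

# Probabilistic tracking

The tracker is deliberately first-order: at each step a candidate
direction is drawn uniformly within a cone (default 45° per step) around
the previous direction and accepted by rejection sampling against the
FOD amplitude, with an envelope derived from the coefficient norm and
the basis addition theorem. We do not reimplement second-order
integration over fibre orientation distributions; the quantitative
contracts here (phantom recovery, density matching, endpoint
localisation) do not require bit-compatibility with any particular
integrator, and the simpler sampler is easier to verify. Propagation is
bidirectional from every seed; arms are concatenated head-to-tail.

Parameters (`tracking_params()`):

| parameter | default | unit | role |
|---|---|---|---|
| `fod_cutoff` | 0.06 | amplitude | minimum FOD amplitude for propagation |
| `min_length` / `max_length` | 5 / 300 | mm | acceptance bounds |
| `step` | half the smallest voxel | mm | step size |
| `max_angle` | 45 | degrees | cone half-angle per step |
| `max_attempts_per_seed` | 1000 | — | global budget multiplier |
| `max_trials` | 50 | — | rejection-sampling draws per step |
| `backtrack` | TRUE | — | truncate-and-resample on rejection |
| `trunc_depth` / `retries` | 3 / 2 | steps / — | backtracking depth and budget |

Seeding is either WM-proportional (voxel drawn with probability
proportional to WM partial volume, position uniform within the voxel) —
a deterministic stand-in for dynamic seeding, which requires an online
density model — or uniform within a mask (used for hippocampus-seeded
tracking; seeding uniformly in the mask rather than on its surface is a
documented choice). All randomness flows through R's RNG, so a
`set.seed()` (or the `seed` parameter) makes runs bit-reproducible.

# SIFT2-style weight fitting

`build_density_system()` assembles the sparse matrix `L[v, s]` of exact
polyline–voxel intersection lengths (mm) and the per-voxel density
target `D[v] = c0(v) · 1/(2√π) · voxel volume`, where `c0` is the l = 0
FOD coefficient. Rows cover voxels with WM + no-priors partial volume
≥ 0.5 *and* non-zero fibre density — the analogue of a SIFT2 processing
mask: a voxel without reconstructed fibre density carries no information
about streamline weights, only about tracking errors, and letting such
voxels dominate the fit destabilises it.

`fit_weights()` minimises

$$ \sum_v \Big(\sum_s w_s L_{vs} - \mu D_v\Big)^2 +
   \lambda\,\bar S \sum_s (\log w_s)^2, \qquad w \ge 0 $$

with two deliberate design choices:

* **μ is fixed by mass matching at the unit-weight baseline**,
  `μ = Σ(L·1)/ΣD`. Treating μ as a free least-squares parameter makes
  `(w, μ) → (c·w, c·μ)` a descent direction of the objective — the joint
  problem's global optimum collapses both to zero and the log penalty
  then compresses genuine weight contrasts. Mass matching removes the
  degeneracy while staying a closed-form proportionality constant.
  A corollary: scaling `D` by `c` scales the fitted μ by `1/c` and
  leaves the weights unchanged.
* **λ is dimensionless.** The log-space Tikhonov penalty is scaled by
  the mean squared density target per streamline,
  `S̄ = Σ(μD)² / n_streamlines`, so the default `λ = 0.01` trades
  comparable quantities regardless of problem size or units. Without
  this, any fixed λ is either negligible (the fit degenerates into a
  sparse non-negative least-squares solution concentrated on a few
  streamlines) or overwhelming (all weights pinned at 1) depending on
  scale.

Optimisation is cyclic exact coordinate descent: each scalar subproblem
`a x² + b x + λ' log²x` is solved by safeguarded Newton. Every
coordinate step is an exact minimisation, so the recorded per-sweep
objective is non-increasing by construction; iteration stops at a
relative change below `tol` (default 1e-8) or `max_iters` sweeps.
Multiplicative (Lee–Seung-style) updates were implemented first and
found to stall far from the minimiser on phantom-scale systems; the
coordinate scheme replaced them.

At λ = 0 the fit reduces to non-negative least squares up to the μ
gauge; tests compare its fitted densities against an independent NNLS
solver. With the default λ, a two-bundle phantom with fibre densities
2:1 and equal streamline counts recovers a per-bundle weight-sum ratio
of 2 within a few percent.

# Connectivity tables

A streamline enters the hippocampus tractogram iff its first or last
point lies in a hippocampus-mask voxel. For each such streamline with
exactly one hippocampal endpoint, its weight is added to the cortical
parcel at the other endpoint (containing voxel's label, else nearest
labelled voxel centre within 2 mm, else dropped and counted) — both to
the `whole` column and to exactly one of `head`/`body`/`tail` according
to the hippocampal endpoint's region. Streamlines with both endpoints in
the hippocampus accumulate in an intra-hippocampal bucket. These rules
make two conservation laws exact by construction, and the tests assert
them: per parcel `head + body + tail = whole`, and the grand total of
parcel sums, intra-hippocampal bucket and dropped weight equals the
tractogram's total weight.

The long axis is a scalar field on the mask (0 anterior tip, 1 posterior
tip, the normalised arc length of the nearest centreline point).
`split_thirds()` partitions with half-open intervals `[0, b1)`,
`[b1, b2)`, `[b2, 1]` (default boundaries 1/3, 2/3); a value exactly at
a boundary belongs to the more posterior region. On real data the
boundaries can be supplied from anatomical landmark planes (uncal apex;
crus of the fornix); the phantom uses the fractional defaults.

Bilateral combination sums the hemispheres (weight sums are extensive
quantities); a mean is available via `how = "mean"`. Percentage columns
report each parcel's share of all cortical connections and of non-MTL
cortical connections, to two decimals.

# Endpoint density maps

`tdi_map()` counts distinct streamlines per fine-grid voxel (each
streamline at most once per voxel); `endpoint_density_map()` bins only
endpoints, optionally restricted to a mask and optionally
weight-summed. The default super-resolution factor is 5 (1 mm phantom
voxels → 0.2 mm fine voxels, mirroring the usual acquisition-to-map
ratio of super-resolved track-density imaging). EDMs are unweighted by
default, with a weighted option. Group averaging is a voxel-wise
arithmetic mean of maps on a common grid — registration to a common
space is out of scope and maps are assumed pre-aligned. Display
windowing maps values below 0.02 to background (inclusive lower
threshold: a value exactly at the threshold is retained), clamps above
0.5, and scales linearly on a 0–0.05 intensity window.

# Long-axis statistics

Per parcel, head/body/tail means across subjects are compared with
paired t tests (head–body, body–tail, head–tail): `t = mean(d)/(sd(d)/√n)`
with the n−1 sample standard deviation, df = n−1, two-sided p. If every
difference is exactly zero the statistic is defined as t = 0, p = 1;
zero variance with non-zero mean is an error. Bonferroni significance
uses the exact threshold `alpha/m` (0.05/3 by default) with strict
inequality; a truncated 0.016 threshold can be had by passing
`alpha = 0.048`.

The four-way pattern classifier is evaluated in precedence order:

1. `gradient_ap` — all three comparisons significant, means increasing
   head < body < tail;
2. `anterior_bias` — head–body not significant, the other two
   significant, tail the lowest mean;
3. `posterior_bias` — head–body and head–tail significant, body–tail
   not, head the lowest mean;
4. `body_bias` — head–body significant and body the largest mean;
5. `other`.

The precedence order matters only for inputs matching several rules;
`body_bias` deliberately tolerates any body–tail / head–tail decision
combination, which covers the observed variants of body-preferring
areas (significant or non-significant body–tail differences).

# The synthetic phantom

The generator builds a 40×40×32 voxel, 1 mm isotropic RAS volume: an
outer zero layer, a CSF shell, a WM interior, a curved hippocampus tube
(radius 2.5 mm) whose long axis runs anterior→posterior with a gentle
medial bow, an optional one-voxel cortical-GM sheet immediately inferior
to the mask (the obstructing interface that motivates the m5TT
amendment), a small subcortical-GM block, and fibre bundles. Each bundle
rises from a 5³-voxel cortical-GM parcel block, pierces the sheet, and
bends smoothly inside the hippocampus to run along the long axis for
~2.5 mm within its declared target segment (entry points at long-axis
fractions 1/6, 0.45 and 0.80 for head, body and tail targets, with the
extension directed away from the nearer segment boundary so endpoint
overshoot stays inside the segment). Painted fibre density falls off
with a 1 mm cosine edge taper — a partial-volume-like soft edge; with
hard-edged tubes the painted density and the achievable streamline
coverage disagree systematically at tube boundaries, which destabilises
weight fitting. Tube voxels outside the hippocampus and sheet are WM;
the hippocampus is cortical GM in the unamended 5TT, so hippocampus
seeds die immediately without the amendment.

Default densities for the three-bundle phantom are 2 (head), 1.5 (body)
and 1 (tail); the two-bundle density-recovery experiment uses 2 and 1
with equal streamline counts seeded from the tube cores (radius − 1 mm),
where coverage is well conditioned.

The generator contains no randomness: a configuration maps to
bit-identical volumes, and the recorded seed only feeds downstream
tracking. What the phantom does *not* emulate: diffusion-weighted signal
formation, noise, distortion, crossing-fibre geometry beyond simple tube
overlaps, two full hemispheres (bilaterality is tested with mirrored
parcel labels), or anatomically realistic hippocampal microstructure.
Passing tests therefore demonstrate the correctness of the pipeline's
computations and contracts, not the biological fidelity of tracking in
real tissue.

# Problem sizes and runtimes

The default study scale used by the test-suite and the acceptance script
is 20,000 whole-volume plus 5,000 hippocampus-seeded streamlines on the
default phantom (about half a minute end to end on one core), 2,000
fixed seeds per arm for the permeation comparison, and 5,000 streamlines
per bundle for the density-recovery experiment. These sizes give
comfortably converged statistics on the phantom; all of them scale
linearly if changed.

# Known limitations

* The tracker is first-order; curvature within a single step is not
  integrated, so very tortuous pathways need a small `step`.
* Voxel-level (not fixel-level) density matching: in voxels containing
  crossing bundles the weight fit constrains total, not per-orientation,
  density.
* `assign_parcel()`'s nearest-labelled-voxel search is exhaustive over
  labelled voxels; for very large parcellations a spatial index would be
  preferable.
* Group-level EDM analysis assumes maps already live on a common grid;
  no registration is provided.
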