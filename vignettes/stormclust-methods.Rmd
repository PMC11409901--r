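---
title: "Methods: nanoscale cluster analysis of dSTORM localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale cluster analysis of dSTORM localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormclust)
```

## The data and the problem

A dSTORM experiment produces, per image, a table of single-molecule
*localizations*: 3D coordinates (nm), a photon count (PC) for the fitted
event, and per-axis localization precisions. Protein aggregates appear as
nanoscale clusters of localizations (radii of roughly 40–200 nm) on top of
a diffuse background of isolated molecules and unspecific events. The
analysis task is: filter unreliable localizations, detect clusters, measure
each cluster (radius, density, localization count), summarise images, and
compare subject groups — with every step deterministic and auditable.

All functions take a data frame of localizations first and return tibbles,
so stages chain with the pipe; clustering adds a `cluster` column
(0 = noise) rather than inventing a new container.

## Quality gates

Three gates run in a fixed order (photon count → precision → PCA), each
only ever removing rows:

* **Photon count** `PC ≥ min_photon_count` (default 1,000 photons,
  inclusive). Localization precision scales as σ ∝ 1/√PC, so dim events
  are the imprecise ones.
* **Precision** `σₓ ≤ max_sigma_x` (default 100 nm, inclusive). The gate
  reads the x-axis precision only; y and z track x closely in practice and
  the single-axis rule keeps the gate interpretable.
* **PCA noise gate.** Per image and channel, the 3D coordinate cloud is
  centred, its covariance eigendecomposed, and localizations outside a
  Mahalanobis radius of `pca_sd_threshold` standard deviations (in the
  principal-axis frame) are removed. We chose a joint (Mahalanobis) gate
  over per-axis trimming because it is rotation-equivariant and has a
  closed-form calibration: on a Gaussian cloud the retained fraction at
  threshold *t* is `pchisq(t^2, df = 3)` — **about 20% at the default
  t = 1**. That default is deliberately strict (it keeps the densest core
  of the image) and is surfaced prominently: set `pca_enabled = FALSE` or
  raise the threshold when the whole field of view matters. Clouds with
  fewer than 4 points or a degenerate covariance pass through unchanged
  with a warning. Whether the gate should act jointly or per axis, and on
  coordinates only or also intensity, is genuinely open; we gate jointly on
  coordinates and flag the choice here.

`precision_pc_correlation()` quantifies the precision–brightness coupling
(Spearman ρ of PC against each σ axis; negative when brighter events are
more precise) and flags constant columns as degenerate rather than
reporting a silent zero.

## DBSCAN

Standard density-based clustering on the 3D Euclidean metric: a core point
has at least `min_pts` neighbors within `eps` nm, **counting itself** (the
convention is pinned and tested; implementations differ). Clusters are
connected components of core points under the ≤ eps relation; non-core
points within eps of a core point join the cluster of their
*lowest-row-index* core neighbor — a deterministic tie-break, so the
partition is a pure function of the table. An optional `z_scale` factor
shrinks the z axis before distances are computed, since axial precision is
typically ~2× worse than lateral.

Defaults `eps = 75` nm and `min_pts = 10` suit the aggregate scale above;
both must be tuned to localization density in real data. Correctness is
established against `dbscan_reference()`, a deliberately naive O(n²)
implementation (full distance matrix, explicit core graph, igraph
components) sharing no code with the grid-accelerated main path; the two
agree exactly — core sets and labels — on randomized mixed instances.

## FOCAL and the photon-count gate

FOCAL bins localizations into cubic voxels (edge `voxel_size`, grid origin
at the per-axis minimum — deterministic; no multi-offset grid averaging).
Each voxel's score is the localization count summed over itself and its
connected neighbors; voxels with score ≥ `minL` are core; connected
components of core voxels with at least `minC` voxels are clusters, and
every localization inside a kept voxel inherits the cluster label.

The photon-count extension removes, **before scoring**, every voxel whose
mean photon count is not strictly greater than `maPC`; scoring, the `minL`
core test, components and `minC` then run on the surviving voxels. This
"gate, then re-run" formulation has three properties we consider essential
and test on arbitrary inputs: with `maPC = 0` it is *exactly* plain FOCAL
(photon counts are positive, so nothing is removed — there is no separate
code path to trust); voxel survival is monotone in `maPC`, so clustered
localization sets are nested as the gate rises; and the `minL` re-test
remains meaningful because pruning faint neighbors lowers the scores of the
voxels that remain. A formulation that gates only inside candidate groups
and re-scores on group voxels alone would break the `maPC = 0` identity
(scores would lose the contribution of non-core neighbors), which is why we
rejected it.

### Parameter defaults and their calibration

The field-of-view, voxel and threshold defaults are the package's own,
chosen once against simulated study conditions and then frozen:

* `voxel_size = 50` nm — 2–3× the 10–20 nm localization precision, small
  enough to resolve 40 nm-σ aggregates.
* `min_l = 15`, `min_c = 2` — on the planted-cluster benchmark (20
  clusters, σ = 30 nm, 200 localizations each, 10% background) cluster
  cores score in the hundreds while background neighborhoods score < 10,
  so detection is insensitive to `min_l` over a wide range.
* **`connectivity = 6` (face adjacency), not 26.** With 50 nm voxels a
  corner adjacency spans √3·50 ≈ 87 nm; stacked on the one-voxel dilation
  introduced by neighborhood scoring, 26-connectivity bridges aggregates
  separated by anything under ~250 nm and merges them. On the benchmark,
  face connectivity raises recall from 0.92 to 0.97 (precision 0.98,
  centroid error ~4 nm) while keeping recovered gyration radii within 6% of
  the analytic σ√3. 26-connectivity remains available
  (`connectivity = 26`) for data where aggregates are sparse.
* The scoring kernel defaults to the neighborhood sum; a self-count kernel
  (`score_kernel = "self"`) detects slightly more reliably but truncates
  cluster tails (gyration radii biased low by ~14% on the benchmark), so it
  is offered only as a sensitivity switch.

`sweep_mapc()` re-runs FOCAL^PC over a vector of gates and tabulates
cluster count, mean radius, mean platform density, localizations per
cluster and the clustered percentage — the standard way to examine how the
gate sharpens detection.

## Cluster metrics

* **Radius** — 3D radius of gyration √(mean squared distance to the
  centroid): deterministic, and far less outlier-sensitive than the largest
  member distance (available as `radius_method = "max_distance"`).
  Singletons have radius 0. For a uniform ball of radius R the gyration
  radius is R√(3/5); for an isotropic Gaussian of spread σ it is σ√3 —
  both used as closed-form oracles in the tests.
* **Density** — the cluster is treated as a sphere of the gyration radius:
  `density_raw = n / ((4/3)πr³)` in nm⁻³, and `density_platform` is exactly
  1,000 × that, a pure display scale. Because aggregate densities are
  quoted per-area as often as per-volume in the SMLM literature, a
  2D-projected `n/(πr²)` column is also emitted; none of the three is ever
  silently substituted for another. Coincident-point clusters (r = 0,
  n ≥ 2) get `NA` densities with a warning rather than infinities, and are
  excluded from means.
* **ROI volume** — convex hull of the image's localizations by default (an
  incremental 3D hull built in-package; volumes match closed forms on
  boxes and simplices and scipy's Qhull on random clouds), with
  bounding-box and user-supplied bounds as alternatives; degenerate
  geometries fall back to the bounding box with a warning. Hulls
  overestimate the "covered volume" of sparse structures, so the
  two-channel module also offers a voxel-occupancy measure (occupied voxel
  count × voxel volume).

## Two-channel ratios

For images stained for both a neuronal marker (PGP9.5) and an aggregate
species (aSyn/p-aSyn), `channel_ratios()` reports marker/aggregate volume
and localization-count ratios per image (marker in the numerator), plus a
volume difference for completeness. Channels are assumed registered by the
microscope; no alignment is attempted. Empty channels yield flagged `NA`
ratios, and `cohort_ratio_table()` joins the cohort manifest, excluding
images missing a channel with a logged warning.

## Group comparison

`mwu_test()` implements the two-sided Mann–Whitney U test with midrank tie
handling. For small samples (`n_A + n_B ≤ 16` in auto mode) the two-sided
p-value is computed by full enumeration of the permutation distribution of
U over all group labelings — exact even with ties, which closed-form exact
formulas are not. Larger samples use the tie-corrected normal approximation
with continuity correction (matching `wilcox.test(correct = TRUE)`, which
serves as an independent cross-check in the tests, not as the
implementation). The reported statistic is min(U_A, U_B); degenerate data
(all values identical) return p = 1 with a flag.

`compare_groups()` compares two groups on any set of per-image metrics at
two levels. The default is the *subject* level: each subject contributes
the mean of its images, which respects the within-subject correlation of
images and matches the small-cohort design (6 vs 6 subjects) this package
targets; the *image* level (each image a point) is also available and the
level is always recorded in the output. p-values are not adjusted —
nonparametric small-cohort studies typically report raw p — but a
Benjamini–Hochberg column (`p_bh`) across the requested metrics is included
for transparency.

## The simulator: what it emulates, and what it does not

`simulate_image()` generates ground-truth scenes: cluster centers uniform
in the ROI with a minimum pairwise separation of 4σ (rejection sampling,
bounded attempts), Poisson member counts, isotropic Gaussian member spread
(true gyration radius σ√3), uniform Poisson background, lognormal photon
counts, and precision coupled as σₓ = s₀/√PC with σ_z = 2σₓ (typical
biplane behaviour). Defaults — 5 × 5 µm × 600 nm ROI, 20 clusters of ~200
localizations at σ = 40 nm, ~10% background, PC ~ lognormal(log 3000, 0.6),
s₀ = 700 nm·√photons giving σₓ ≈ 10–16 nm — are desk-scale study
conditions, not a fit to any particular dataset.

Within a cluster, photon counts are boosted by a Gaussian radial profile
peaking at `cluster_pc_multiplier` (default 2.5×) in the core and decaying
to the background level at the rim, with lognormal per-cluster variation of
the peak. Bright, dense aggregate cores are the physical premise of the
maPC gate (brighter events are the precisely localized ones, and they
concentrate where the label is dense); a spatially flat in-cluster boost
would make the gate prune voxels *randomly* within a cluster, which thins
clusters without shrinking them. With the radial profile, the 5,000-photon
gate cuts at ~1.6σ from the core, so sweeps over maPC 0 → 2,500 → 5,000
show the expected monotone trends (radii down, densities up).

`simulate_cohort()` adds the hierarchy (groups → subjects → images) with
lognormal subject random effects on the expected cluster count and
group-effect multipliers applied to group B; all effects at 1 gives an
exchangeable null cohort used for the type-I-error check.
`simulate_two_channel()` co-centers a stated fraction of channel B clusters
on channel A's.

Not emulated: blinking/repeat localizations of single fluorophores, drift,
anisotropic or fibrillar aggregate shapes, chromatic mis-registration, and
detector-level noise. Passing tests on this simulator therefore validate
the *algorithms and their calibration*, not the biology of any particular
tissue; real data will have correlated localizations (blinking) that
inflate apparent densities, which no test here detects.

## Numerical and degenerate-input policy

Thresholds are inclusive (`≥ min`, `≤ max`); the maPC gate is strict
(`> maPC`) — both conventions documented where they apply. Cluster labels
are canonicalized by first appearance in row order, so identical inputs
give identical outputs and row permutations change labels only by
permutation. Empty tables flow through every stage as empty results;
images emptied by filtering still appear in pipeline summaries with zero
counts and `NA` means. The convex hull normalizes coordinates to the unit
box before any orientation predicate (tolerance 1e-10 in normalized
units) and reports `NA` for clouds with no 3D hull, triggering the
bounding-box fallback. Manifest validation rejects duplicate image ids and
subjects assigned to both groups.

## Problem sizes used in the checks

The shipped verification suite runs at deliberately modest scale, chosen as
the smallest sizes at which the statistical assertions are stable:
clustering oracle comparisons on ~100–200-point instances (100 instances
for DBSCAN, 50 for FOCAL), maPC trends pooled over 5 scenes of ~8,000
localizations, planted-cluster recovery over 3–10 scenes of 20 clusters,
calibration laws at n = 10,000, and the null-cohort rejection rate over 200
replicates of 6 + 6 subjects × 10 small images. All randomness is seeded.

## Known limitations

* FOCAL cannot separate aggregates whose member clouds overlap at the voxel
  scale; at σ = 30 nm spreads, pairs closer than ~150 nm may merge even
  with face connectivity. That is a resolution limit of grid clustering,
  not a bug, and is visible in the ~0.97 (not 1.0) planted recall.
* The gyration-radius/sphere density model understates the volume of
  elongated clusters.
* The convex-hull ROI volume is generous for hollow or curved structures
  (e.g. a gland section's shell); the voxel-occupancy alternative is
  tighter but voxel-size dependent.
* Exact MWU enumeration grows combinatorially; beyond `n_A + n_B = 16` the
  normal approximation is used (the crossover is configurable).
* The PCA gate assumes one dominant structure per image; fields containing
  several well-separated structures will see peripheral ones removed at
  strict thresholds.
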