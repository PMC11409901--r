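# stormclust

Cluster analysis of 3D dSTORM single-molecule localization data, built for
quantifying nanoscale protein aggregates — for example alpha-synuclein
(aSyn) and its Ser129-phosphorylated form in skin-biopsy nerve tissue, where
aggregate radius, density and abundance are candidate biomarkers of
Parkinson's disease. The package is aimed at microscopists and analysts who
have per-image localization tables (3D coordinates, photon counts,
localization precisions) from software such as VutaraSRX or ThunderSTORM
and want reproducible aggregate statistics and group comparisons.

## What it computes

Localizations are quality-filtered with three gates: a minimum photon count
(PC ≥ 1,000 by default, since dim localizations have poor precision), a
maximum x-precision (σₓ ≤ 100 nm), and an optional PCA-based spatial gate
that keeps localizations within a Mahalanobis radius of *t* standard
deviations of the image's coordinate cloud (retention on a Gaussian cloud is
the χ²₃ CDF at *t*²).

Two cluster detectors are provided:

* **DBSCAN** — a point with ≥ `min_pts` neighbors within `eps` nm is a core
  point; clusters are density-connected components of core points; the rest
  within reach are border points, all others noise.
* **FOCAL / FOCAL^PC** — localizations are binned into cubic voxels of edge
  `voxel_size` nm; a voxel's score is the localization count in itself and
  its connected neighbors; voxels with score ≥ `minL` are core, and
  connected components of core voxels with ≥ `minC` voxels are clusters.
  The FOCAL^PC extension adds a photon-count gate: voxels whose *mean* PC is
  not strictly above `maPC` are removed before scoring, so only bright —
  hence precisely localized — regions survive. `maPC = 0` reduces exactly to
  plain FOCAL, and raising `maPC` can only shrink clusters.

Each cluster gets a radius (3D radius of gyration,
r = √(mean ‖xᵢ − x̄‖²)), a spherical volume, a localization count, and
densities: raw n/(4⁄3 π r³) in nm⁻³, the same ×1,000 on the platform scale,
and a 2D-projected n/(π r²). Per-image summaries normalize localization
counts by the region-of-interest volume (convex hull by default). For
two-channel images, the package reports marker/aggregate (e.g.
PGP9.5/aSyn) volume and count ratios. Cohorts are compared with an exact
two-sided Mann–Whitney U test (full enumeration of the rank permutation
distribution, valid with ties), by default at the subject level: each
subject contributes the mean of its images.

A seeded simulator generates ground-truth images — Gaussian nano-clusters
(gyration radius = σ√3) over uniform background, lognormal photon counts
with bright cluster cores, precision coupled as σ = s₀/√PC — so every stage
can be validated against known truth.

## Worked example

```r
library(stormclust)

sim <- simulate_image(n_clusters = 20, locs_per_cluster = 200,
                      cluster_sigma = 40, seed = 1)
locs <- apply_quality_filters(sim$locs, filter_config(pca_enabled = FALSE))
assigned <- cluster_focal(locs, voxel_size = 50, min_l = 15, min_c = 2)
summarize_image(assigned)
#> # A tibble: 1 × 9
#>   image_id n_clusters mean_radius mean_density_platform mean_locs_per_cluster
#> 1 sim-001          19        65.1                 0.169                  177.
#>   pct_locs_clustered n_localizations_total   roi_volume locs_per_roi_volume
#> 1               76.2                  4407 13423016299.         0.000000328
```

19 of the 20 planted clusters are found (two nearby clusters merged), with
a mean gyration radius of 65 nm against the planted 40·√3 ≈ 69 nm, and 76%
of localizations assigned to clusters. Sweeping the photon-count gate shows
the FOCAL^PC behaviour — radii shrink and densities grow as faint rim
voxels are discarded:

```r
sweep_mapc(locs, c(0, 2500, 5000))
#>   ma_pc n_clusters mean_radius mean_density_platform mean_locs_per_cluster pct_locs_clustered
#> 1     0         19        65.1                 0.169                 177.                76.2
#> 2  2500         19        64.1                 0.172                 172.                74.0
#> 3  5000         21        48.0                 0.186                  93.2               44.4

mwu_test(c(1, 2, 3), c(4, 5, 6))
#> Mann-Whitney U test (two-sided)
#> U = 0 (U_A = 0, U_B = 9), n = 3 vs 3, p = 0.1 [exact]
```

End-to-end cohort runs (`run_pipeline()`) take a YAML/JSON config and write
per-cluster metrics, image summaries, two-channel ratios, group comparisons
and a provenance record; `inst/scripts/dstorm-tools.R` exposes the same
stages as shell subcommands (`simulate | filter | cluster | metrics |
ratios | compare | run`).

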