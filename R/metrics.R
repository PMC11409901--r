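#' Cluster radius from member coordinates
#'
#' The cluster "radius" is the 3D radius of gyration: the root-mean-square
#' Euclidean distance of the members to their centroid. It is deterministic
#' and far less outlier-sensitive than the maximum member distance, which is
#' available as an alternative definition for sensitivity analyses. A
#' singleton cluster has radius 0.
#'
#' @param coords Numeric matrix with columns x, y, z (nm), one row per
#'   member.
#' @param method `"gyration"` (default) or `"max_distance"` (largest member
#'   distance to the centroid).
#' @return Radius in nm.
#' @examples
#' cluster_radius(rbind(c(0, 0, 0), c(100, 0, 0))) # 50
#' @export
cluster_radius <- function(coords, method = c("gyration", "max_distance")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) abort("cluster_radius needs at least one member")
  ctr <- colMeans(coords)
  d2 <- rowSums(sweep(coords, 2, ctr, "-")^2)
  switch(method,
    gyration = sqrt(mean(d2)),
    max_distance = sqrt(max(d2))
  )
}

#' Cluster density from localization count and radius
#'
#' The 3D density treats the cluster as a sphere with the gyration radius:
#' `density_raw = n / ((4/3) * pi * radius^3)` in localizations/nm^3. For
#' convenient plotting scales, `density_platform = 1000 * density_raw`
#' exactly. A 2D-projected density `n / (pi * radius^2)` (localizations/nm^2)
#' is also reported, since aggregate densities are quoted in both unit
#' systems in the SMLM literature.
#'
#' @param n_locs Number of localizations in the cluster (>= 2).
#' @param radius Cluster radius in nm. A zero radius (coincident points)
#'   yields `NA` densities with a warning rather than an infinity.
#' @return A tibble with `density_raw`, `density_platform`, `density_2d`.
#' @export
cluster_density <- function(n_locs, radius) {
  stopifnot(length(n_locs) == length(radius))
  bad <- radius <= 0 & n_locs >= 2
  if (any(bad)) {
    warn("cluster(s) with coincident members have undefined density (radius 0); returning NA")
  }
  raw <- ifelse(radius > 0, n_locs / ((4 / 3) * pi * radius^3), NA_real_)
  tibble(
    density_raw = raw,
    density_platform = 1000 * raw,
    density_2d = ifelse(radius > 0, n_locs / (pi * radius^2), NA_real_)
  )
}

#' Per-cluster morphometrics
#'
#' Computes one record per detected cluster from a clustered localization
#' table (output of [cluster_dbscan()] or [cluster_focal()]): localization
#' count, centroid, radius, spherical volume and densities. Noise
#' localizations (`cluster == 0`) are ignored.
#'
#' @param locs A localization tibble with a `cluster` column.
#' @param radius_method See [cluster_radius()].
#' @return A tibble with columns `image_id`, `cluster`, `n_locs`, `cx`, `cy`,
#'   `cz`, `radius` (nm), `volume` (nm^3), `density_raw`, `density_platform`
#'   (= 1000 x raw, exactly) and `density_2d`.
#' @export
summarize_clusters <- function(locs, radius_method = c("gyration", "max_distance")) {
  radius_method <- match.arg(radius_method)
  locs <- as_tibble(locs)
  if (!"cluster" %in% names(locs)) {
    abort("locs must carry a 'cluster' column (run a clustering step first)")
  }
  if (!"image_id" %in% names(locs)) locs$image_id <- "image"
  members <- dplyr::filter(locs, .data$cluster > 0)
  if (nrow(members) == 0) {
    return(tibble(
      image_id = character(), cluster = integer(), n_locs = integer(),
      cx = double(), cy = double(), cz = double(), radius = double(),
      volume = double(), density_raw = double(), density_platform = double(),
      density_2d = double()
    ))
  }
  recs <- members |>
    group_by(.data$image_id, .data$cluster) |>
    summarise(
      n_locs = n(),
      cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
      radius = cluster_radius(cbind(.data$x, .data$y, .data$z), radius_method),
      .groups = "drop"
    ) |>
    arrange(.data$image_id, .data$cluster)
  dens <- cluster_density(recs$n_locs, recs$radius)
  recs$volume <- (4 / 3) * pi * recs$radius^3
  bind_cols_safe(recs, dens)
}

bind_cols_safe <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- b[[nm]]
  a
}

#' Region-of-interest volume of a localization table
#'
#' The ROI volume normalizes per-image localization counts so that images
#' with differently sized fields of view are comparable. Three estimators are
#' provided: the convex hull of the coordinates (default; the tightest
#' deterministic convex proxy for the imaged structure), the axis-aligned
#' bounding box, and user-supplied bounds. When a convex hull does not exist
#' (fewer than 4 non-coplanar points) the bounding box is used with a
#' warning.
#'
#' @param locs A localization tibble.
#' @param method `"convex_hull"`, `"bounding_box"` or `"user_bounds"`.
#' @param bounds For `"user_bounds"`: list with numeric `min` and `max`
#'   length-3 vectors (nm).
#' @return Volume in nm^3.
#' @export
roi_volume <- function(locs, method = c("convex_hull", "bounding_box", "user_bounds"),
                       bounds = NULL) {
  method <- match.arg(method)
  locs <- as_tibble(locs)
  if (method == "user_bounds") {
    if (is.null(bounds) || is.null(bounds$min) || is.null(bounds$max)) {
      abort("user_bounds requires bounds = list(min = c(x,y,z), max = c(x,y,z))")
    }
    ext <- bounds$max - bounds$min
    if (any(ext <= 0)) abort("user bounds have zero or negative extent")
    return(prod(ext))
  }
  if (nrow(locs) == 0) abort("cannot compute an ROI volume for an empty table")
  coords <- as.matrix(locs[, c("x", "y", "z")])
  if (method == "convex_hull") {
    v <- convex_hull_volume(coords)
    if (!is.na(v)) return(v)
    warn("degenerate geometry for convex hull; falling back to bounding box")
  }
  prod(apply(coords, 2, function(v) diff(range(v))))
}

#' Per-image summary of clustering results
#'
#' Aggregates the per-cluster records of each image into the quantities used
#' for cohort-level comparison: cluster count, mean radius, mean platform
#' density, mean localizations per cluster, the percentage of localizations
#' assigned to clusters, and the ROI-volume-normalized localization count.
#'
#' @param locs A clustered localization tibble (with `cluster` column).
#' @param roi_method,bounds Passed to [roi_volume()].
#' @param radius_method Passed to [summarize_clusters()].
#' @return A tibble with one row per image: `image_id`, `n_clusters`,
#'   `mean_radius`, `mean_density_platform`, `mean_locs_per_cluster`,
#'   `pct_locs_clustered`, `n_localizations_total`, `roi_volume`,
#'   `locs_per_roi_volume`.
#' @export
summarize_image <- function(locs, roi_method = "convex_hull", bounds = NULL,
                            radius_method = "gyration") {
  locs <- as_tibble(locs)
  if (!"cluster" %in% names(locs)) {
    abort("locs must carry a 'cluster' column (run a clustering step first)")
  }
  if (!"image_id" %in% names(locs)) locs$image_id <- "image"
  recs <- summarize_clusters(locs, radius_method = radius_method)
  purrr::map_dfr(split(locs, locs$image_id), function(img) {
    id <- img$image_id[1]
    r <- dplyr::filter(recs, .data$image_id == id)
    total <- nrow(img)
    vol <- roi_volume(img, roi_method, bounds = bounds)
    tibble(
      image_id = id,
      n_clusters = nrow(r),
      mean_radius = if (nrow(r)) mean(r$radius) else NA_real_,
      mean_density_platform = if (nrow(r)) mean(r$density_platform, na.rm = TRUE) else NA_real_,
      mean_locs_per_cluster = if (nrow(r)) mean(r$n_locs) else NA_real_,
      pct_locs_clustered = 100 * sum(img$cluster > 0) / total,
      n_localizations_total = total,
      roi_volume = vol,
      locs_per_roi_volume = total / vol
    )
  })
}
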