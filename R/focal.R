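# voxel-grid clustering; connectivity kernels shared by scoring and
# component search live in conn_offsets()

# per-localization integer voxel indices (0-based) for a cubic grid anchored
# at the per-axis minimum coordinate
focal_voxel_index <- function(locs, voxel_size, origin = NULL) {
  if (is.null(origin)) origin <- c(min(locs$x), min(locs$y), min(locs$z))
  list(
    ix = as.integer(floor((locs$x - origin[1]) / voxel_size)),
    iy = as.integer(floor((locs$y - origin[2]) / voxel_size)),
    iz = as.integer(floor((locs$z - origin[3]) / voxel_size)),
    origin = origin
  )
}

conn_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  offs
}

#' Bin localizations into a cubic voxel grid
#'
#' Partitions a localization table into cubic voxels of edge `voxel_size` nm.
#' The grid origin is the per-axis minimum coordinate, and every localization
#' maps to exactly one voxel via `floor((coord - origin) / voxel_size)`.
#'
#' @param locs A localization tibble (non-empty).
#' @param voxel_size Cubic voxel edge length in nm (> 0).
#' @return A tibble with one row per occupied voxel: integer indices `vx`,
#'   `vy`, `vz`, the localization count `n_locs`, and `mean_pc`, the mean
#'   photon count of the localizations in the voxel. The grid `origin` and
#'   `voxel_size` are attached as attributes.
#' @export
voxelize <- function(locs, voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("voxel_size must be a single positive number")
  }
  locs <- as_tibble(locs)
  if (nrow(locs) == 0) abort("cannot voxelize an empty localization table")
  vi <- focal_voxel_index(locs, voxel_size)
  out <- tibble(vx = vi$ix, vy = vi$iy, vz = vi$iz,
                pc = locs$photon_count) |>
    group_by(.data$vx, .data$vy, .data$vz) |>
    summarise(n_locs = n(), mean_pc = mean(.data$pc), .groups = "drop")
  attr(out, "origin") <- vi$origin
  attr(out, "voxel_size") <- voxel_size
  out
}

#' FOCAL / FOCAL-PC voxel-grid clustering
#'
#' Grid-based cluster detection for SMLM data (FOCAL), with an optional
#' photon-count gate (the FOCAL-PC extension). The algorithm:
#'
#' 1. bin localizations into cubic voxels of edge `voxel_size` nm;
#' 2. when `ma_pc > 0`, discard voxels whose mean photon count is not
#'    strictly greater than `ma_pc` (the *maPC* gate; `ma_pc = 0` keeps every
#'    voxel since photon counts are positive, reducing exactly to plain
#'    FOCAL);
#' 3. score every surviving voxel as the total localization count in itself
#'    and its (26- or 6-connected) surviving neighbors;
#' 4. voxels with score `>= min_l` are core voxels;
#' 5. clusters are connected components of core voxels with at least `min_c`
#'    voxels;
#' 6. every localization inside a kept voxel receives that cluster's label,
#'    all others are noise.
#'
#' Because the maPC gate removes voxels before scoring, raising `ma_pc` can
#' only shrink clusters: the set of clustered localizations is nested
#' (monotone non-increasing) in `ma_pc`.
#'
#' @param locs A (filtered) localization tibble.
#' @param voxel_size Cubic voxel edge, nm. The 50 nm default is 2-3x the
#'   typical 10-20 nm dSTORM localization precision.
#' @param min_l Minimum neighborhood localization score for a core voxel.
#' @param min_c Minimum number of voxels per cluster.
#' @param ma_pc Minimum average photon count per voxel (photons); voxels must
#'   exceed it strictly. 0 disables the gate (plain FOCAL).
#' @param connectivity 6 (face-adjacent voxels, default) or 26 (faces +
#'   edges + corners), used both for scoring neighborhoods and for connected
#'   components. At 50 nm voxels a corner adjacency spans ~87 nm, enough to
#'   bridge distinct aggregates separated by under ~250 nm; face connectivity
#'   keeps nearby aggregates apart and is the calibrated default.
#' @param score_kernel `"neighborhood"` (default: voxel + connected
#'   neighbors) or `"self"` (the voxel's own count only) for the core score.
#' @return The input tibble with an integer `cluster` column (0 = noise) and
#'   a `"clustering"` attribute with the full parameter provenance.
#' @seealso [focal_reference()] for the independently coded oracle,
#'   [sweep_mapc()] for maPC parameter sweeps.
#' @export
cluster_focal <- function(locs, voxel_size = 50, min_l = 15, min_c = 2,
                          ma_pc = 0, connectivity = c(6, 26),
                          score_kernel = c("neighborhood", "self")) {
  connectivity <- as.numeric(connectivity)[1]
  if (!connectivity %in% c(26, 6)) abort("connectivity must be 26 or 6")
  score_kernel <- match.arg(score_kernel)
  stopifnot(voxel_size > 0, min_l >= 1, min_c >= 1, ma_pc >= 0)
  locs <- as_tibble(locs)
  params <- list(voxel_size = voxel_size, min_l = min_l, min_c = min_c,
                 ma_pc = ma_pc, connectivity = connectivity,
                 score_kernel = score_kernel)
  algorithm <- if (ma_pc > 0) "focal_pc" else "focal"
  res <- per_image_assignment(locs, function(img) {
    list(labels = focal_labels_one(img, voxel_size, min_l, min_c, ma_pc,
                                   connectivity, score_kernel))
  })
  attach_assignment(locs, res$labels, algorithm, params)
}

focal_labels_one <- function(locs, voxel_size, min_l, min_c, ma_pc,
                             connectivity, score_kernel) {
  n <- nrow(locs)
  if (n == 0) return(integer(0))

  vi <- focal_voxel_index(locs, voxel_size)
  loc_key <- paste(vi$ix, vi$iy, vi$iz)
  vox <- tibble(key = loc_key, pc = locs$photon_count) |>
    group_by(.data$key) |>
    summarise(n_locs = n(), mean_pc = mean(.data$pc), .groups = "drop")

  # maPC gate: strictly greater-than, applied before scoring
  vox <- vox[vox$mean_pc > ma_pc, , drop = FALSE]
  if (nrow(vox) == 0) return(integer(n))

  idx <- do.call(rbind, lapply(strsplit(vox$key, " ", fixed = TRUE), as.integer))
  counts <- setNames(vox$n_locs, vox$key)

  score <- vox$n_locs
  if (score_kernel == "neighborhood") {
    offs <- conn_offsets(connectivity)
    for (r in seq_len(nrow(offs))) {
      nb_key <- paste(idx[, 1] + offs[r, 1], idx[, 2] + offs[r, 2],
                      idx[, 3] + offs[r, 3])
      hit <- counts[nb_key]
      hit[is.na(hit)] <- 0
      score <- score + unname(hit)
    }
  }

  core <- score >= min_l
  if (!any(core)) return(integer(n))
  core_key <- vox$key[core]
  core_idx <- idx[core, , drop = FALSE]
  nc <- length(core_key)

  # connected components of core voxels
  offs <- conn_offsets(connectivity)
  half <- offs[offs[, 1] > 0 |
                 (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(half))) {
    nb_key <- paste(core_idx[, 1] + half[r, 1], core_idx[, 2] + half[r, 2],
                    core_idx[, 3] + half[r, 3])
    j <- match(nb_key, core_key)
    hit <- which(!is.na(j))
    if (length(hit) > 0) edges <- c(edges, rbind(hit, j[hit]))
  }
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_c)
  comp_label <- ifelse(comp$membership %in% keep_comp, comp$membership, 0L)

  labels <- integer(n)
  m <- match(loc_key, core_key)
  assigned <- !is.na(m)
  labels[assigned] <- comp_label[m[assigned]]
  canonical_labels(as.integer(labels))
}

#' Literal dense-array FOCAL implementation (oracle)
#'
#' An independently coded transcription of the FOCAL / FOCAL-PC steps used by
#' [cluster_focal()], written against a dense 3D array with explicit
#' offset-shifted additions and a flood-fill connected-component search. It
#' shares no code with [cluster_focal()] and exists to verify it; it is
#' memory-hungry on large fields of view.
#'
#' @inheritParams cluster_focal
#' @return Same shape of result as [cluster_focal()].
#' @export
focal_reference <- function(locs, voxel_size = 50, min_l = 15, min_c = 2,
                            ma_pc = 0, connectivity = c(6, 26),
                            score_kernel = c("neighborhood", "self")) {
  connectivity <- as.numeric(connectivity)[1]
  score_kernel <- match.arg(score_kernel)
  locs <- as_tibble(locs)
  params <- list(voxel_size = voxel_size, min_l = min_l, min_c = min_c,
                 ma_pc = ma_pc, connectivity = connectivity,
                 score_kernel = score_kernel)
  algorithm <- if (ma_pc > 0) "focal_pc_reference" else "focal_reference"
  res <- per_image_assignment(locs, function(img) {
    list(labels = focal_reference_labels(img, voxel_size, min_l, min_c, ma_pc,
                                         connectivity, score_kernel))
  })
  attach_assignment(locs, res$labels, algorithm, params)
}

focal_reference_labels <- function(locs, voxel_size, min_l, min_c, ma_pc,
                                   connectivity, score_kernel) {
  n <- nrow(locs)
  if (n == 0) return(integer(0))

  vi <- focal_voxel_index(locs, voxel_size)
  ix <- vi$ix + 1L; iy <- vi$iy + 1L; iz <- vi$iz + 1L
  dims <- c(max(ix), max(iy), max(iz))
  if (prod(dims) > 5e7) abort("focal_reference grid too large")
  counts <- array(0, dims)
  pcsum <- array(0, dims)
  for (i in seq_len(n)) {
    counts[ix[i], iy[i], iz[i]] <- counts[ix[i], iy[i], iz[i]] + 1
    pcsum[ix[i], iy[i], iz[i]] <- pcsum[ix[i], iy[i], iz[i]] + locs$photon_count[i]
  }
  occupied <- counts > 0
  meanpc <- array(0, dims)
  meanpc[occupied] <- pcsum[occupied] / counts[occupied]
  survive <- occupied & (meanpc > ma_pc)
  gated <- counts
  gated[!survive] <- 0

  pad <- array(0, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- gated
  score <- array(0, dims)
  kernel_offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (r in seq_len(nrow(kernel_offsets))) {
    dx <- kernel_offsets$dx[r]; dy <- kernel_offsets$dy[r]; dz <- kernel_offsets$dz[r]
    manh <- abs(dx) + abs(dy) + abs(dz)
    if (score_kernel == "self" && manh > 0) next
    if (connectivity == 6 && manh > 1) next
    score <- score + pad[(2:(dims[1] + 1)) + dx,
                         (2:(dims[2] + 1)) + dy,
                         (2:(dims[3] + 1)) + dz, drop = FALSE]
  }

  core <- survive & (score >= min_l)
  comp <- array(0L, dims)
  offs <- conn_offsets(connectivity)
  cid <- 0L
  core_cells <- which(core, arr.ind = TRUE)
  for (s in seq_len(nrow(core_cells))) {
    start <- core_cells[s, ]
    if (comp[start[1], start[2], start[3]] != 0L) next
    cid <- cid + 1L
    queue <- matrix(start, nrow = 1)
    comp[start[1], start[2], start[3]] <- cid
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nbr <- cur + c(offs[r, 1], offs[r, 2], offs[r, 3])
        if (any(nbr < 1) || any(nbr > dims)) next
        if (core[nbr[1], nbr[2], nbr[3]] && comp[nbr[1], nbr[2], nbr[3]] == 0L) {
          comp[nbr[1], nbr[2], nbr[3]] <- cid
          queue <- rbind(queue, nbr)
        }
      }
    }
  }
  if (cid > 0) {
    sizes <- tabulate(comp[comp > 0L], nbins = cid)
    drop_ids <- which(sizes < min_c)
    if (length(drop_ids) > 0) comp[comp %in% drop_ids] <- 0L
  }
  labels <- integer(n)
  for (i in seq_len(n)) labels[i] <- comp[ix[i], iy[i], iz[i]]
  canonical_labels(labels)
}

#' Sweep the maPC gate and summarise each run
#'
#' Runs [cluster_focal()] once per value of `ma_pc` and returns the per-image
#' aggregate metrics for each run, which is the standard way to examine how
#' the photon-count gate sharpens cluster detection: as maPC rises, fewer and
#' denser voxels survive, so cluster radii shrink and densities grow.
#'
#' @param locs A (filtered) localization tibble for one image.
#' @param ma_pc_values Numeric vector of maPC gates to apply (photons,
#'   non-negative).
#' @param ... Passed to [cluster_focal()] (`voxel_size`, `min_l`, `min_c`,
#'   ...).
#' @param radius_method Cluster radius definition, see [summarize_clusters()].
#' @return A tibble with one row per maPC value: `ma_pc`, `n_clusters`,
#'   `mean_radius`, `mean_density_platform`, `mean_locs_per_cluster`,
#'   `pct_locs_clustered`.
#' @export
sweep_mapc <- function(locs, ma_pc_values, ..., radius_method = "gyration") {
  if (length(ma_pc_values) == 0) abort("ma_pc_values must be non-empty")
  if (any(ma_pc_values < 0)) abort("ma_pc_values must be non-negative")
  purrr::map_dfr(ma_pc_values, function(mp) {
    assigned <- cluster_focal(locs, ma_pc = mp, ...)
    recs <- summarize_clusters(assigned, radius_method = radius_method)
    tibble(
      ma_pc = mp,
      n_clusters = nrow(recs),
      mean_radius = if (nrow(recs)) mean(recs$radius) else NA_real_,
      mean_density_platform = if (nrow(recs)) {
        mean(recs$density_platform, na.rm = TRUE)
      } else {
        NA_real_
      },
      mean_locs_per_cluster = if (nrow(recs)) mean(recs$n_locs) else NA_real_,
      pct_locs_clustered = 100 * sum(assigned$cluster > 0) / max(1L, nrow(assigned))
    )
  })
}
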