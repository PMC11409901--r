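# Neighbor search on a uniform grid of cell edge eps: candidate neighbors of
# a point can only lie in its own or the 26 adjacent cells.
eps_neighbor_lists <- function(pts, eps) {
  n <- nrow(pts)
  nb <- vector("list", n)
  if (n == 0) return(nb)
  cell <- floor(sweep(pts, 2, apply(pts, 2, min), "-") / eps)
  storage.mode(cell) <- "integer"
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  eps2 <- eps^2
  for (idx in cells) {
    ctr <- cell[idx[1], ]
    cand_keys <- paste(ctr[1] + offs[, 1], ctr[2] + offs[, 2], ctr[3] + offs[, 3])
    cand <- unlist(cells[intersect(cand_keys, names(cells))], use.names = FALSE)
    a <- pts[idx, , drop = FALSE]
    b <- pts[cand, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    for (r in seq_along(idx)) {
      nb[[idx[r]]] <- sort(cand[d2[r, ] <= eps2 + 1e-9])
    }
  }
  nb
}

# Relabel cluster ids so that clusters are numbered 1..k in order of their
# first member row; keeps output deterministic and permutation-friendly.
canonical_labels <- function(labels) {
  pos <- which(labels > 0)
  if (length(pos) == 0) return(labels)
  first <- vapply(split(pos, labels[pos]), min, integer(1))
  remap <- integer(max(labels))
  remap[as.integer(names(first))[order(first)]] <- seq_along(first)
  labels[pos] <- remap[labels[pos]]
  labels
}

attach_assignment <- function(locs, labels, algorithm, params, core = NULL) {
  out <- as_tibble(locs)
  out$cluster <- labels
  if (!is.null(core)) out$core <- core
  attr(out, "clustering") <- list(algorithm = algorithm, params = params)
  out
}

# apply a per-image labelling function over a (possibly multi-image) table;
# images are independent coordinate frames and are never clustered jointly.
# `fun` returns list(labels = <int, canonical>, core = <logical or NULL>).
per_image_assignment <- function(locs, fun) {
  n <- nrow(locs)
  labels <- integer(n)
  core <- logical(n)
  has_core <- FALSE
  ids <- if ("image_id" %in% names(locs)) locs$image_id else rep("image", n)
  for (idx in split(seq_len(n), factor(ids, levels = unique(ids)))) {
    res <- fun(locs[idx, , drop = FALSE])
    labels[idx] <- res$labels
    if (!is.null(res$core)) {
      core[idx] <- res$core
      has_core <- TRUE
    }
  }
  list(labels = labels, core = if (has_core) core else NULL)
}

#' DBSCAN clustering of localizations
#'
#' Density-based spatial clustering of the 3D localization coordinates with
#' the standard DBSCAN semantics: a *core* localization has at least
#' `min_pts` neighbors within `eps` nm (the point itself counts); clusters
#' are the density-connected components of core points; remaining points
#' within `eps` of a core point are border points, all others noise.
#'
#' Border points are deterministically assigned to the cluster of their
#' lowest-row-index core neighbor, so the output is a pure function of the
#' input table and parameters.
#'
#' @param locs A (filtered) localization tibble.
#' @param eps Neighborhood radius in nm.
#' @param min_pts Minimum number of neighbors (self-inclusive) for a core
#'   point.
#' @param z_scale Optional scaling applied to the z axis before computing
#'   distances, to compensate for the poorer axial precision (default 1 =
#'   isotropic 3D metric).
#'
#' Multi-image tables (distinct `image_id` values) are clustered per image:
#' images are independent coordinate frames, and cluster ids restart at 1
#' within each image.
#' @return The input tibble with an integer `cluster` column (0 = noise,
#'   clusters numbered 1..k by order of first appearance), a logical `core`
#'   column, and a `"clustering"` attribute recording algorithm and
#'   parameters.
#' @seealso [dbscan_reference()] for the brute-force oracle.
#' @export
cluster_dbscan <- function(locs, eps, min_pts, z_scale = 1) {
  stopifnot(eps > 0, min_pts >= 1)
  locs <- as_tibble(locs)
  params <- list(eps = eps, min_pts = min_pts, z_scale = z_scale)
  res <- per_image_assignment(locs, function(img) {
    dbscan_labels_one(img, eps, min_pts, z_scale)
  })
  attach_assignment(locs, res$labels, "dbscan", params, core = res$core)
}

dbscan_labels_one <- function(locs, eps, min_pts, z_scale) {
  n <- nrow(locs)
  if (n == 0) return(list(labels = integer(0), core = logical(0)))
  pts <- cbind(locs$x, locs$y, locs$z * z_scale)
  nb <- eps_neighbor_lists(pts, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    head_ptr <- 1L
    while (head_ptr <= length(queue)) {
      j <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      nbrs <- nb[[j]]
      nbrs <- nbrs[core[nbrs] & labels[nbrs] == 0L]
      if (length(nbrs) > 0) {
        labels[nbrs] <- cid
        queue <- c(queue, nbrs)
      }
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn) > 0) labels[i] <- labels[min(cn)]
  }
  list(labels = canonical_labels(labels), core = core)
}

#' Brute-force density-reachability clustering (DBSCAN oracle)
#'
#' A deliberately naive O(n^2) implementation of the same clustering contract
#' as [cluster_dbscan()]: it materialises the full pairwise distance matrix,
#' computes the core-point set, builds the explicit core-core adjacency graph
#' and takes its connected components, then attaches border points to the
#' cluster of their lowest-index core neighbor. It shares no code with
#' [cluster_dbscan()] and exists to verify it on small instances.
#'
#' @inheritParams cluster_dbscan
#' @return Same shape of result as [cluster_dbscan()].
#' @export
dbscan_reference <- function(locs, eps, min_pts, z_scale = 1) {
  stopifnot(eps > 0, min_pts >= 1)
  locs <- as_tibble(locs)
  params <- list(eps = eps, min_pts = min_pts, z_scale = z_scale)
  res <- per_image_assignment(locs, function(img) {
    n <- nrow(img)
    if (n == 0) return(list(labels = integer(0), core = logical(0)))
    if (n > 10000) abort("dbscan_reference is quadratic; refusing n > 10,000")
    pts <- cbind(img$x, img$y, img$z * z_scale)
    d <- as.matrix(stats::dist(pts))
    within <- d <= eps + 1e-9
    core <- unname(rowSums(within) >= min_pts)  # diagonal TRUE: self-inclusive
    labels <- integer(n)
    core_idx <- which(core)
    if (length(core_idx) > 0) {
      adj <- within[core_idx, core_idx, drop = FALSE]
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      comp <- igraph::components(g)$membership
      labels[core_idx] <- comp
      for (i in which(!core)) {
        cn <- core_idx[within[i, core_idx]]
        if (length(cn) > 0) labels[i] <- labels[min(cn)]
      }
    }
    list(labels = canonical_labels(as.integer(labels)), core = core)
  })
  attach_assignment(locs, res$labels, "dbscan_reference", params,
                    core = res$core)
}
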