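place_cluster_centers <- function(n_clusters, roi_extent, min_separation,
                                  margin, fixed = NULL) {
  centers <- fixed
  if (is.null(centers)) centers <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  max_attempts <- 1000L * max(1L, n_clusters)
  while (nrow(centers) < n_clusters) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("ROI too small to place cluster centers at the required separation")
    }
    cand <- runif(3, min = margin, max = roi_extent - margin)
    if (any(roi_extent - 2 * margin <= 0)) {
      abort("ROI extent smaller than twice the cluster margin")
    }
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand, "-")^2))) >= min_separation) {
      centers <- rbind(centers, cand)
    }
  }
  unname(centers)
}

#' Simulate one dSTORM localization image with ground truth
#'
#' Generates a synthetic 3D localization table emulating the structure of a
#' dSTORM image of protein aggregates: isotropic Gaussian nano-clusters on a
#' uniform background, photon counts drawn from a lognormal distribution
#' (brighter inside clusters), and localization precisions coupled to photon
#' count through the photon-limited scaling `sigma = s0 / sqrt(PC)` with the
#' axial precision a fixed multiple of the lateral one. Every localization
#' carries its true cluster label, so clustering runs can be scored for
#' precision and recall.
#'
#' Cluster centers are placed uniformly in the ROI with a minimum pairwise
#' separation (rejection sampling), and the per-cluster localization count is
#' Poisson. With an isotropic Gaussian spread of `cluster_sigma` nm, the true
#' radius of gyration of a cluster is `cluster_sigma * sqrt(3)`.
#'
#' @param image_id Image identifier.
#' @param roi_extent Length-3 numeric, ROI edge lengths in nm. The default
#'   (5 x 5 um laterally, 600 nm axially) matches a typical biplane dSTORM
#'   field of view.
#' @param n_clusters Number of planted clusters.
#' @param locs_per_cluster Mean localizations per cluster (Poisson).
#' @param cluster_sigma Isotropic Gaussian spread of cluster members, nm.
#' @param background_density Uniform background localization density,
#'   localizations/nm^3.
#' @param pc_meanlog,pc_sdlog Lognormal photon-count parameters (log
#'   photons).
#' @param cluster_pc_multiplier Peak photon-count multiplier at the cluster
#'   center (clustered emitters sit in denser label environments and fit
#'   brighter); the boost decays with a Gaussian radial profile of scale
#'   `cluster_sigma`, reaching the background brightness at the rim.
#' @param cluster_pc_sdlog Log-SD of the per-cluster peak multiplier,
#'   creating photon-count heterogeneity across clusters.
#' @param precision_s0 Precision coupling constant, nm * sqrt(photons):
#'   `sigma_x = precision_s0 / sqrt(PC)`.
#' @param axial_factor `sigma_z = axial_factor * sigma_x` (default 2, typical
#'   of biplane detection).
#' @param channel Channel label for all localizations.
#' @param min_separation Minimum pairwise distance between cluster centers,
#'   nm; defaults to `4 * cluster_sigma`.
#' @param centers Optional matrix of fixed cluster centers (used for
#'   co-centered two-channel simulations); remaining centers are placed
#'   randomly.
#' @param seed Integer seed; fixed seed gives bit-identical output. `NULL`
#'   uses the current RNG state.
#' @return A list with `locs` (localization tibble with a `true_cluster`
#'   column, 0 = background) and `clusters` (tibble of true centers, spread
#'   and member counts).
#' @export
simulate_image <- function(image_id = "sim-001",
                           roi_extent = c(5000, 5000, 600),
                           n_clusters = 20,
                           locs_per_cluster = 200,
                           cluster_sigma = 40,
                           background_density = 3e-8,
                           pc_meanlog = log(3000),
                           pc_sdlog = 0.6,
                           cluster_pc_multiplier = 2.5,
                           cluster_pc_sdlog = 0.25,
                           precision_s0 = 700,
                           axial_factor = 2,
                           channel = "default",
                           min_separation = 4 * cluster_sigma,
                           centers = NULL,
                           seed = NULL) {
  stopifnot(length(roi_extent) == 3, all(roi_extent > 0), n_clusters >= 0,
            locs_per_cluster >= 0, cluster_sigma > 0, background_density >= 0,
            precision_s0 > 0, axial_factor > 0)
  run <- function() {
    margin <- min(2 * cluster_sigma, min(roi_extent) / 4)
    if (n_clusters > 0) {
      ctr <- place_cluster_centers(n_clusters, roi_extent, min_separation,
                                   margin, fixed = centers)
    } else {
      ctr <- matrix(numeric(0), ncol = 3)
    }
    n_members <- if (n_clusters > 0) rpois(n_clusters, locs_per_cluster) else integer(0)
    bright <- if (n_clusters > 0) {
      cluster_pc_multiplier * exp(rnorm(n_clusters, 0, cluster_pc_sdlog))
    } else {
      numeric(0)
    }
    m <- sum(n_members)
    k <- rep(seq_len(n_clusters), n_members)
    dx <- rnorm(m, 0, cluster_sigma)
    dy <- rnorm(m, 0, cluster_sigma)
    dz <- rnorm(m, 0, cluster_sigma)
    # brightness peaks at the cluster core and decays to the background
    # level at the rim (dense label environments fit brighter)
    boost <- 1 + (bright[k] - 1) *
      exp(-(dx^2 + dy^2 + dz^2) / (2 * cluster_sigma^2))
    n_bg <- rpois(1, background_density * prod(roi_extent))
    x <- c(ctr[k, 1] + dx, runif(n_bg, 0, roi_extent[1]))
    y <- c(ctr[k, 2] + dy, runif(n_bg, 0, roi_extent[2]))
    z <- c(ctr[k, 3] + dz, runif(n_bg, 0, roi_extent[3]))
    pc <- c(rlnorm(m, pc_meanlog, pc_sdlog) * boost,
            rlnorm(n_bg, pc_meanlog, pc_sdlog))
    true_cluster <- c(k, integer(n_bg))
    total <- m + n_bg
    sigma_x <- precision_s0 / sqrt(pc)
    locs <- tibble::new_tibble(list(
      image_id = rep(image_id, total),
      x = x, y = y, z = z,
      photon_count = pc,
      sigma_x = sigma_x, sigma_y = sigma_x, sigma_z = axial_factor * sigma_x,
      frame = if (total) sample(0:2999, total, replace = TRUE) else integer(),
      channel = rep(channel, total),
      true_cluster = as.integer(true_cluster)
    ), nrow = total)
    clusters <- tibble::new_tibble(list(
      image_id = rep(image_id, n_clusters),
      cluster = seq_len(n_clusters),
      cx = if (n_clusters) ctr[, 1] else double(),
      cy = if (n_clusters) ctr[, 2] else double(),
      cz = if (n_clusters) ctr[, 3] else double(),
      sigma = rep(cluster_sigma, n_clusters),
      n_locs = as.integer(n_members)
    ), nrow = n_clusters)
    list(locs = locs, clusters = clusters)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a two-group, multi-subject cohort
#'
#' Generates a hierarchical cohort: subjects within two groups, several
#' images per subject, with subject-level lognormal random effects on the
#' expected cluster count and group-level effect multipliers applied to
#' group B. Effect multipliers of 1 make the groups exchangeable (a null
#' cohort for type-I-error checks).
#'
#' @param subjects_per_group Named integer vector, e.g. `c(A = 6, B = 6)`.
#' @param images_per_subject Images per subject.
#' @param effect_n_clusters,effect_cluster_sigma,effect_background
#'   Multipliers applied to group B's expected cluster count, cluster spread
#'   and background density.
#' @param subject_sdlog Log-SD of the subject-level random effect on the
#'   expected cluster count.
#' @param seed Integer seed for the whole cohort.
#' @param ... Base image parameters passed to [simulate_image()].
#' @return A list with `locs` (all images bound into one tibble), `manifest`
#'   (image_id, subject_id, group, channel) and `clusters` (true cluster
#'   records for every image).
#' @export
simulate_cohort <- function(subjects_per_group = c(A = 6, B = 6),
                            images_per_subject = 10,
                            effect_n_clusters = 1,
                            effect_cluster_sigma = 1,
                            effect_background = 1,
                            subject_sdlog = 0.15,
                            seed = NULL, ...) {
  base <- list(...)
  subjects_per_group <- unlist(subjects_per_group)
  groups <- names(subjects_per_group)
  if (is.null(groups)) groups <- LETTERS[seq_along(subjects_per_group)]
  run <- function() {
    locs <- list(); man <- list(); clus <- list()
    i <- 0L
    for (g in seq_along(subjects_per_group)) {
      grp <- groups[g]
      eff_n <- if (g == 2) effect_n_clusters else 1
      eff_s <- if (g == 2) effect_cluster_sigma else 1
      eff_b <- if (g == 2) effect_background else 1
      for (s in seq_len(subjects_per_group[g])) {
        subject_id <- sprintf("%s%02d", grp, s)
        subj_mult <- exp(rnorm(1, 0, subject_sdlog))
        for (im in seq_len(images_per_subject)) {
          i <- i + 1L
          image_id <- sprintf("%s-img%02d", subject_id, im)
          args <- base
          args$image_id <- image_id
          args$n_clusters <- rpois(
            1, (base$n_clusters %||% 20) * eff_n * subj_mult
          )
          args$cluster_sigma <- (base$cluster_sigma %||% 40) * eff_s
          args$background_density <- (base$background_density %||% 3e-8) * eff_b
          args$seed <- NULL
          sim <- do.call(simulate_image, args)
          locs[[i]] <- sim$locs
          clus[[i]] <- sim$clusters
          man[[i]] <- tibble(
            image_id = image_id, subject_id = subject_id, group = grp,
            channel = base$channel %||% "default"
          )
        }
      }
    }
    list(
      locs = bind_rows(locs),
      manifest = validate_manifest(bind_rows(man)),
      clusters = bind_rows(clus)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a registered two-channel image pair
#'
#' Generates two channels over a shared ROI, with a stated fraction of
#' channel B's clusters co-centered on channel A clusters (emulating
#' aggregate species sitting on labelled nerve fibers). Localization counts
#' per cluster are independently Poisson in each channel.
#'
#' @param image_id Shared image identifier.
#' @param config_a,config_b Named lists of [simulate_image()] arguments for
#'   each channel (channel labels default to `"PGP9.5"` and `"aSyn"`).
#' @param overlap_fraction Fraction of channel B clusters co-centered with
#'   channel A clusters, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `locs` (both channels in one tibble), `clusters_a`
#'   and `clusters_b`.
#' @export
simulate_two_channel <- function(image_id = "sim-2ch-001",
                                 config_a = list(),
                                 config_b = list(),
                                 overlap_fraction = 1,
                                 seed = NULL) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("overlap_fraction must be in [0, 1]")
  }
  run <- function() {
    config_a$image_id <- image_id
    config_a$channel <- config_a$channel %||% "PGP9.5"
    config_a$seed <- NULL
    sim_a <- do.call(simulate_image, config_a)

    config_b$image_id <- image_id
    config_b$channel <- config_b$channel %||% "aSyn"
    config_b$seed <- NULL
    n_b <- config_b$n_clusters %||% 20
    n_shared <- min(round(overlap_fraction * n_b), nrow(sim_a$clusters))
    if (n_shared > 0) {
      config_b$centers <- as.matrix(
        sim_a$clusters[seq_len(n_shared), c("cx", "cy", "cz")]
      )
    }
    sim_b <- do.call(simulate_image, config_b)
    list(
      locs = bind_rows(sim_a$locs, sim_b$locs),
      clusters_a = sim_a$clusters,
      clusters_b = sim_b$clusters
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Score a clustering run against simulation ground truth
#'
#' Matches detected cluster centroids to the true planted centers (greedy
#' nearest match within `max_dist`) and reports recovery statistics.
#'
#' @param detected Per-cluster records from [summarize_clusters()].
#' @param truth True cluster tibble from [simulate_image()].
#' @param max_dist Maximum centroid-to-center distance (nm) for a match.
#' @return A list with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `mean_centroid_error` (nm over matches) and `matches` (a
#'   tibble of matched pairs).
#' @export
score_cluster_recovery <- function(detected, truth, max_dist = 50) {
  truth <- dplyr::filter(as_tibble(truth), .data$n_locs > 0)
  n_true <- nrow(truth)
  n_det <- nrow(detected)
  if (n_true == 0 || n_det == 0) {
    return(list(n_true = n_true, n_detected = n_det, n_matched = 0L,
                recall = if (n_true == 0) NA_real_ else 0,
                precision = if (n_det == 0) NA_real_ else 0,
                mean_centroid_error = NA_real_,
                matches = tibble(true_cluster = integer(),
                                 detected_cluster = integer(),
                                 dist = double())))
  }
  d <- sqrt(outer(truth$cx, detected$cx, "-")^2 +
              outer(truth$cy, detected$cy, "-")^2 +
              outer(truth$cz, detected$cz, "-")^2)
  matches <- list()
  used_t <- logical(n_true); used_d <- logical(n_det)
  repeat {
    d_open <- d
    d_open[used_t, ] <- Inf
    d_open[, used_d] <- Inf
    best <- which.min(d_open)
    if (length(best) == 0 || !is.finite(d_open[best])) break
    if (d_open[best] > max_dist) break
    ti <- (best - 1) %% n_true + 1
    di <- (best - 1) %/% n_true + 1
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    matches[[length(matches) + 1]] <- tibble(
      true_cluster = truth$cluster[ti],
      detected_cluster = detected$cluster[di],
      dist = d[ti, di]
    )
    if (all(used_t) || all(used_d)) break
  }
  m <- bind_rows(matches)
  if (nrow(m) == 0) {
    m <- tibble(true_cluster = integer(), detected_cluster = integer(),
                dist = double())
  }
  list(
    n_true = n_true, n_detected = n_det, n_matched = nrow(m),
    recall = nrow(m) / n_true, precision = nrow(m) / n_det,
    mean_centroid_error = if (nrow(m)) mean(m$dist) else NA_real_,
    matches = m
  )
}
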