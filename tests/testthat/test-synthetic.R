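test_that("a fixed seed gives bit-identical output", {
  a <- simulate_image(seed = 101)
  b <- simulate_image(seed = 101)
  expect_identical(a$locs, b$locs)
  expect_identical(a$clusters, b$clusters)
  c <- simulate_image(seed = 102)
  expect_false(identical(a$locs, c$locs))
})

test_that("degenerate configs: empty scene, clusters only, background only", {
  empty <- simulate_image(n_clusters = 0, background_density = 0, seed = 1)
  expect_equal(nrow(empty$locs), 0)

  pure <- simulate_image(n_clusters = 5, background_density = 0, seed = 2)
  expect_setequal(unique(pure$locs$true_cluster), 1:5)
  expect_equal(nrow(pure$clusters), 5)

  bg <- simulate_image(n_clusters = 0, background_density = 1e-7, seed = 3)
  expect_true(all(bg$locs$true_cluster == 0))
})

test_that("true members have gyration radius cluster_sigma * sqrt(3)", {
  sim <- simulate_image(n_clusters = 4, locs_per_cluster = 5000,
                        cluster_sigma = 30, background_density = 0,
                        roi_extent = c(4000, 4000, 1500), seed = 4)
  for (k in 1:4) {
    m <- sim$locs[sim$locs$true_cluster == k, ]
    rg <- cluster_radius(cbind(m$x, m$y, m$z))
    expect_equal(rg, 30 * sqrt(3), tolerance = 0.05)
  }
})

test_that("background density and photon-count scale are recovered", {
  roi <- c(3000, 3000, 1000)
  dens <- 5e-6
  sim <- simulate_image(n_clusters = 0, background_density = dens,
                        roi_extent = roi, seed = 5)
  n <- nrow(sim$locs)
  lambda <- dens * prod(roi)
  expect_lt(abs(n - lambda), 5 * sqrt(lambda))

  # lognormal mean exp(mu + sigma^2/2)
  expect_equal(mean(sim$locs$photon_count), exp(log(3000) + 0.6^2 / 2),
               tolerance = 0.05)
})

test_that("precision follows sigma = s0 / sqrt(PC) with 2x axial penalty", {
  sim <- simulate_image(n_clusters = 3, seed = 6)
  locs <- sim$locs
  expect_equal(locs$sigma_x, 700 / sqrt(locs$photon_count))
  expect_equal(locs$sigma_z, 2 * locs$sigma_x)
  fit <- lm(log(sigma_x) ~ log(photon_count), data = locs)
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 1e-10)
  rho <- precision_pc_correlation(locs)
  expect_equal(rho$rho[rho$axis == "sigma_x"], -1)
})

test_that("cluster centers respect the ROI and the minimum separation", {
  sim <- simulate_image(n_clusters = 15, cluster_sigma = 40,
                        roi_extent = c(3000, 3000, 600), seed = 7)
  ctr <- as.matrix(sim$clusters[, c("cx", "cy", "cz")])
  expect_true(all(ctr >= 0 & ctr <= rep(c(3000, 3000, 600), each = 15)))
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_gte(min(d), 4 * 40)

  expect_error(
    simulate_image(n_clusters = 50, cluster_sigma = 100,
                   roi_extent = c(800, 800, 200), seed = 8),
    "ROI too small|margin"
  )
})

test_that("cohort generation is hierarchical, complete and manifest-consistent", {
  sim <- simulate_cohort(
    subjects_per_group = c(A = 6, B = 6), images_per_subject = 10,
    n_clusters = 2, locs_per_cluster = 20, background_density = 1e-9,
    roi_extent = c(1200, 1200, 400), seed = 9
  )
  expect_equal(nrow(sim$manifest), 120)
  expect_equal(length(unique(sim$manifest$subject_id)), 12)
  expect_setequal(unique(sim$manifest$group), c("A", "B"))
  # every localization belongs to a manifest image; sparse configs may leave
  # the occasional image empty, so the manifest is the authority
  expect_true(all(unique(sim$locs$image_id) %in% sim$manifest$image_id))
  expect_gte(length(unique(sim$locs$image_id)), 110)
})

test_that("two-channel overlap plants shared and unshared centers", {
  cfg <- list(n_clusters = 8, locs_per_cluster = 50, background_density = 0)
  full <- simulate_two_channel(config_a = cfg, config_b = cfg,
                               overlap_fraction = 1, seed = 10)
  expect_equal(full$clusters_b[, c("cx", "cy", "cz")],
               full$clusters_a[, c("cx", "cy", "cz")])

  none <- simulate_two_channel(config_a = cfg, config_b = cfg,
                               overlap_fraction = 0, seed = 11)
  shared <- intersect(
    paste(none$clusters_a$cx, none$clusters_a$cy),
    paste(none$clusters_b$cx, none$clusters_b$cy)
  )
  expect_equal(length(shared), 0)

  expect_error(simulate_two_channel(overlap_fraction = 1.2), "overlap_fraction")
})

test_that("a planted 1:2 localization-count ratio is recovered", {
  cfg_a <- list(n_clusters = 10, locs_per_cluster = 100, background_density = 0)
  cfg_b <- list(n_clusters = 10, locs_per_cluster = 200, background_density = 0)
  sim <- simulate_two_channel(config_a = cfg_a, config_b = cfg_b,
                              overlap_fraction = 1, seed = 12)
  r <- channel_ratios(sim$locs)
  expect_equal(r$count_ratio, 0.5, tolerance = 0.1)  # Poisson error at n=1000
})

test_that("recovery scoring matches truth to detections sensibly", {
  sim <- simulate_image(n_clusters = 10, locs_per_cluster = 200,
                        cluster_sigma = 30,
                        background_density = 1e-9, seed = 13)
  detected <- summarize_clusters(cluster_focal(sim$locs))
  sc <- score_cluster_recovery(detected, sim$clusters, max_dist = 50)
  expect_gte(sc$recall, 0.9)
  expect_lte(sc$n_matched, min(sc$n_true, sc$n_detected))
  # perfect self-match
  self <- detected
  self$cx <- detected$cx; self$cy <- detected$cy; self$cz <- detected$cz
  truth_like <- tibble::tibble(cluster = detected$cluster, cx = detected$cx,
                               cy = detected$cy, cz = detected$cz,
                               n_locs = detected$n_locs)
  sc2 <- score_cluster_recovery(detected, truth_like, max_dist = 1)
  expect_equal(sc2$recall, 1)
  expect_equal(sc2$mean_centroid_error, 0)
})
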