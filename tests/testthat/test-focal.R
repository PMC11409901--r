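# locs laid out so that each group of rows lands in a known voxel
voxel_block <- function(voxel_ix, n, pc, voxel_size = 50) {
  x0 <- voxel_ix * voxel_size
  toy_locs(seq(x0 + 5, x0 + 45, length.out = n), y = 10, z = 10, pc = pc)
}

test_that("voxelize bins by floor((coord - origin)/voxel_size)", {
  locs <- toy_locs(c(0, 49, 51))
  vg <- voxelize(locs, 50)
  expect_equal(nrow(vg), 2)
  expect_equal(sort(vg$n_locs), c(1, 2))

  one <- toy_locs(7, pc = 3210)
  vg1 <- voxelize(one, 50)
  expect_equal(vg1$n_locs, 1)
  expect_equal(vg1$mean_pc, 3210)

  expect_error(voxelize(locs, 0), "voxel_size")
})

test_that("voxel counts conserve localizations on a uniform cube", {
  locs <- withr::with_seed(9, toy_locs(
    runif(20000, 0, 1000), runif(20000, 0, 1000), runif(20000, 0, 1000)
  ))
  vg <- voxelize(locs, 100)
  expect_equal(sum(vg$n_locs), 20000)
  expect_equal(nrow(vg), 1000)  # 10 x 10 x 10 occupied at this density
})

test_that("a single dense blob within one voxel is one cluster with all members", {
  locs <- withr::with_seed(10, toy_locs(
    runif(300, 60, 90), runif(300, 10, 40), runif(300, 10, 40)
  ))
  out <- cluster_focal(locs, voxel_size = 50, min_l = 10, min_c = 1)
  expect_equal(unique(out$cluster), 1)
  expect_equal(sum(out$cluster == 1), 300)
})

test_that("sparse implementation matches the dense literal transcription", {
  for (seed in 1:50) {
    locs <- random_blob_instance(seed + 200)
    for (mp in c(0, 2500)) {
      a <- cluster_focal(locs, voxel_size = 50, min_l = 10, min_c = 2, ma_pc = mp)
      b <- focal_reference(locs, voxel_size = 50, min_l = 10, min_c = 2, ma_pc = mp)
      expect_identical(a$cluster, b$cluster)
    }
  }
})

test_that("a zero maPC gate is inert: photon counts cannot influence plain FOCAL", {
  for (seed in 1:50) {
    locs <- random_blob_instance(seed + 300)
    plain <- cluster_focal(locs, voxel_size = 50, min_l = 10, min_c = 2, ma_pc = 0)
    # same geometry, photon counts replaced wholesale: identical partition
    flat <- locs
    flat$photon_count <- rep(1, nrow(locs))
    gate_stub <- cluster_focal(flat, voxel_size = 50, min_l = 10, min_c = 2,
                               ma_pc = 0)
    expect_identical(plain$cluster, gate_stub$cluster)
    # and the run is deterministic
    expect_identical(plain$cluster,
                     cluster_focal(locs, voxel_size = 50, min_l = 10,
                                   min_c = 2, ma_pc = 0)$cluster)
  }
})

test_that("maPC gate drops faint voxels from a candidate cluster", {
  # four adjacent voxels along x with per-voxel mean PCs 3000,3000,900,800
  locs <- dplyr::bind_rows(
    voxel_block(0, 20, 3000), voxel_block(1, 20, 3000),
    voxel_block(2, 20, 900), voxel_block(3, 20, 800)
  )
  plain <- cluster_focal(locs, voxel_size = 50, min_l = 30, min_c = 2, ma_pc = 0)
  expect_true(all(plain$cluster == 1))  # one 4-voxel cluster without the gate

  gated <- cluster_focal(locs, voxel_size = 50, min_l = 30, min_c = 2,
                         ma_pc = 2500)
  expect_equal(gated$cluster, rep(c(1L, 0L), c(40, 40)))
})

test_that("raising maPC shrinks clustered sets monotonically (nesting)", {
  sim <- simulate_image(cluster_pc_multiplier = 2.5, seed = 21)
  gates <- c(0, 1000, 2500, 5000)
  assigned <- lapply(gates, function(mp) cluster_focal(sim$locs, ma_pc = mp))
  for (i in seq_len(length(gates) - 1)) {
    inner <- assigned[[i + 1]]$cluster > 0
    outer <- assigned[[i]]$cluster > 0
    expect_true(all(outer[inner]))
  }
})

test_that("translation by whole voxels leaves the partition unchanged", {
  sim <- simulate_image(n_clusters = 5, locs_per_cluster = 80, seed = 22)
  base <- cluster_focal(sim$locs, voxel_size = 50)
  shifted <- sim$locs
  shifted$x <- shifted$x + 5 * 50
  shifted$y <- shifted$y - 3 * 50
  shifted$z <- shifted$z + 1 * 50
  out <- cluster_focal(shifted, voxel_size = 50)
  expect_identical(out$cluster, base$cluster)
})

test_that("labels are a valid assignment: one label each, contiguous ids", {
  sim <- simulate_image(n_clusters = 8, seed = 23)
  out <- cluster_focal(sim$locs)
  expect_equal(length(out$cluster), nrow(sim$locs))
  k <- max(out$cluster)
  expect_setequal(unique(out$cluster[out$cluster > 0]), seq_len(k))
  expect_equal(sum(out$cluster > 0) + sum(out$cluster == 0), nrow(out))
})

test_that("sweep_mapc is a faithful per-gate summary", {
  sim <- simulate_image(n_clusters = 6, seed = 24)
  one <- sweep_mapc(sim$locs, 0)
  direct <- summarize_clusters(cluster_focal(sim$locs, ma_pc = 0))
  expect_equal(one$n_clusters, nrow(direct))
  expect_equal(one$mean_radius, mean(direct$radius))

  twice <- sweep_mapc(sim$locs, c(0, 0))
  expect_equal(twice[1, ], twice[2, ])

  expect_error(sweep_mapc(sim$locs, numeric(0)), "non-empty")
  expect_error(sweep_mapc(sim$locs, -5), "non-negative")
})

test_that("empty input yields an empty assignment", {
  out <- cluster_focal(toy_locs(numeric(0)))
  expect_equal(nrow(out), 0)
  expect_true("cluster" %in% names(out))
})
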