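test_that("photon-count gate keeps hand-counted survivors, inclusively", {
  locs <- toy_locs(1:4, pc = c(500, 1200, 1500, 900))
  out <- filter_photon_count(locs, 1000)
  expect_equal(out$photon_count, c(1200, 1500))
  expect_equal(filter_photon_count(locs, 0), locs)       # identity at 0
  expect_equal(nrow(filter_photon_count(locs, 1e6)), 0)  # all below
  expect_equal(filter_photon_count(toy_locs(1, pc = 1000), 1000)$x, 1)
})

test_that("precision gate keeps hand-counted survivors, inclusively", {
  locs <- toy_locs(1:3, sigma_x = c(20, 99, 101))
  expect_equal(filter_precision(locs, 100)$sigma_x, c(20, 99))
  expect_equal(filter_precision(locs, Inf), locs)
  expect_equal(nrow(filter_precision(toy_locs(numeric(0)), 100)), 0)
  expect_equal(filter_precision(toy_locs(1, sigma_x = 100), 100)$x, 1)
})

test_that("row filters are idempotent, commute, and only ever subset", {
  for (seed in 1:5) {
    locs <- withr::with_seed(seed, toy_locs(
      rnorm(200), pc = rlnorm(200, log(1200), 0.8),
      sigma_x = rlnorm(200, log(60), 0.6)
    ))
    f1 <- filter_photon_count(locs, 1000)
    f2 <- filter_precision(locs, 100)
    expect_identical(filter_photon_count(f1, 1000), f1)
    expect_identical(filter_precision(f2, 100), f2)
    ab <- filter_precision(f1, 100)
    ba <- filter_photon_count(f2, 1000)
    expect_identical(ab, ba)
    expect_true(all(ab$x %in% locs$x))
  }
})

test_that("PCA gate retention on an isotropic Gaussian matches chi-square(3)", {
  locs <- withr::with_seed(11, toy_locs(
    rnorm(10000, 0, 50), rnorm(10000, 0, 50), rnorm(10000, 0, 50)
  ))
  kept <- filter_pca_noise(locs, sd_threshold = 1)
  expect_lt(abs(nrow(kept) / nrow(locs) - pchisq(1, df = 3)), 0.02)
})

test_that("PCA gate edge cases: infinite threshold, tiny and collinear clouds", {
  locs <- withr::with_seed(2, toy_locs(rnorm(50), rnorm(50), rnorm(50)))
  expect_identical(filter_pca_noise(locs, Inf), locs)

  tiny <- toy_locs(1:3)
  expect_warning(out <- filter_pca_noise(tiny, 1), ">= 4")
  expect_identical(out, tiny)

  line <- toy_locs(1:20, y = 2 * (1:20), z = 3 * (1:20))
  expect_warning(out <- filter_pca_noise(line, 1), "degenerate")
  expect_identical(out, line)
})

test_that("PCA gate operates per image so clouds do not contaminate each other", {
  a <- withr::with_seed(3, toy_locs(rnorm(500), rnorm(500), rnorm(500),
                                    image_id = "a"))
  b <- withr::with_seed(4, toy_locs(rnorm(500, 1e6), rnorm(500), rnorm(500),
                                    image_id = "b"))
  both <- dplyr::bind_rows(a, b)
  kept <- filter_pca_noise(both, 1)
  # each image keeps ~ pchisq(1,3) of its own cloud, not 50% of a bimodal one
  expect_gt(sum(kept$image_id == "a"), 50)
  expect_gt(sum(kept$image_id == "b"), 50)
})

test_that("precision-PC correlation: perfect monotone, independent, constant", {
  mono <- toy_locs(1:3, pc = c(100, 400, 1600), sigma_x = c(40, 20, 10))
  out <- precision_pc_correlation(mono)
  expect_equal(out$rho[out$axis == "sigma_x"], -1)

  indep <- withr::with_seed(5, toy_locs(
    1:1000, pc = rlnorm(1000, log(2000), 0.5),
    sigma_x = rlnorm(1000, log(20), 0.3)
  ))
  expect_lt(abs(precision_pc_correlation(indep)$rho[1]), 0.1)

  const <- toy_locs(1:10, pc = c(1:10 * 100), sigma_x = 15)
  out <- precision_pc_correlation(const)
  expect_true(out$degenerate[out$axis == "sigma_x"])
  expect_true(is.na(out$rho[out$axis == "sigma_x"]))

  expect_error(precision_pc_correlation(toy_locs(1:2)), "at least 3")
})

test_that("filter chain runs in documented order and logs counts", {
  locs <- withr::with_seed(6, toy_locs(
    rnorm(500), rnorm(500), rnorm(500),
    pc = rlnorm(500, log(1500), 0.7),
    sigma_x = rlnorm(500, log(60), 0.6)
  ))
  out <- apply_quality_filters(locs, filter_config())
  log <- attr(out, "filter_log")
  expect_equal(log$stage, c("photon_count", "precision", "pca_noise"))
  expect_equal(log$n_before[1], 500)
  expect_equal(log$n_after[3], nrow(out))
  # stages only ever shrink the table
  expect_true(all(log$n_after <= log$n_before))

  no_pca <- apply_quality_filters(locs, filter_config(pca_enabled = FALSE))
  expect_equal(nrow(attr(no_pca, "filter_log")), 2)
})
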