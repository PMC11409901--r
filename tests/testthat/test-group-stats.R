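test_that("fully separated 3v3 samples: U = 0, exact two-sided p = 0.1", {
  t <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 0.1)
  expect_equal(t$mode_used, "exact")
  # independent implementation agrees
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(t$p_value, w$p.value)
})

test_that("identical samples are degenerate with p = 1", {
  t <- mwu_test(rep(2, 4), rep(2, 5))
  expect_true(t$degenerate)
  expect_equal(t$p_value, 1)
  expect_equal(t$statistic, 4 * 5 / 2)  # all ties: U = n_a n_b / 2
})

test_that("exact mode equals wilcox.test's exact p for all n_a + n_b <= 10", {
  set.seed(17)
  for (n_a in 1:7) {
    for (n_b in 1:(10 - n_a)) {
      if (n_b < 1) next
      a <- round(rnorm(n_a), 6)
      b <- round(rnorm(n_b, 0.5), 6)  # tie-free with prob 1
      t <- mwu_test(a, b, mode = "exact")
      w <- wilcox.test(a, b, exact = TRUE)
      expect_equal(t$p_value, w$p.value,
                   info = sprintf("n_a=%d n_b=%d", n_a, n_b))
      expect_equal(max(t$u_a, t$u_b), max(w$statistic, n_a * n_b - w$statistic))
    }
  }
})

test_that("swapping groups maps U_A to n_A n_B - U_A and preserves p", {
  set.seed(18)
  a <- rnorm(6); b <- rnorm(7, 0.8)
  fwd <- mwu_test(a, b)
  rev <- mwu_test(b, a)
  expect_equal(rev$u_a, 6 * 7 - fwd$u_a)
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(rev$statistic, fwd$statistic)
})

test_that("p is invariant under strictly monotone transforms", {
  set.seed(19)
  a <- rlnorm(5); b <- rlnorm(6, 0.5)
  expect_equal(mwu_test(a, b)$p_value, mwu_test(log(a), log(b))$p_value)
  expect_equal(mwu_test(a, b)$p_value, mwu_test(a^3, b^3)$p_value)
})

test_that("normal approximation matches wilcox.test with tie correction", {
  set.seed(20)
  a <- round(rnorm(40), 1)  # rounding induces ties
  b <- round(rnorm(45, 0.3), 1)
  t <- mwu_test(a, b, mode = "normal_approx")
  w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(t$p_value, w$p.value, tolerance = 1e-10)
})

test_that("tidy and glance return one-row summaries", {
  t <- mwu_test(1:4, 3:8)
  td <- generics::tidy(t)
  expect_equal(nrow(td), 1)
  expect_equal(td$p.value, t$p_value)
  expect_identical(generics::glance(t), td)
})

test_that("compare_groups aggregates to subject means before testing", {
  # 3 vs 3 subjects, 2 images each, non-overlapping subject means
  data <- tibble::tibble(
    image_id = paste0("i", 1:12),
    subject_id = rep(paste0("s", 1:6), each = 2),
    group = rep(c("A", "B"), each = 6),
    m = c(1, 1.2, 2, 2.1, 3, 3.3, 4, 4.4, 5, 5.2, 6, 6.1)
  )
  cmp <- compare_groups(data, metrics = "m", level = "subject")
  expect_equal(cmp$n_a, 3)
  expect_equal(cmp$u, 0)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$level, "subject")

  img <- compare_groups(data, metrics = "m", level = "image")
  expect_equal(img$n_a, 6)
  expect_lt(img$p_value, cmp$p_value)
})

test_that("compare_groups validates groups and metrics", {
  data <- tibble::tibble(
    image_id = "i1", subject_id = "s1", group = "A", m = 1
  )
  expect_error(compare_groups(data, metrics = "m"), "two groups")
  data2 <- dplyr::bind_rows(data, tibble::tibble(
    image_id = "i2", subject_id = "s2", group = "B", m = 2
  ))
  expect_error(compare_groups(data2, metrics = "nope"), "nope")
  cmp <- compare_groups(data2, metrics = "m")
  expect_true(all(c("p_bh", "median_a", "mode") %in% names(cmp)))
})

test_that("a planted 30% cluster-count effect is usually detected at 6v6", {
  hits <- vapply(1:15, function(r) {
    sim <- simulate_cohort(
      subjects_per_group = c(A = 6, B = 6), images_per_subject = 10,
      effect_n_clusters = 1.3,
      n_clusters = 5, locs_per_cluster = 40, cluster_sigma = 30,
      background_density = 2e-9, roi_extent = c(1500, 1500, 400),
      seed = 4000 + r
    )
    clustered <- cluster_focal(sim$locs, voxel_size = 50, min_l = 10, min_c = 2)
    counts <- summarize_clusters(clustered) |>
      dplyr::count(image_id, name = "n_detected") |>
      dplyr::right_join(dplyr::distinct(sim$manifest, image_id),
                        by = "image_id") |>
      dplyr::mutate(n_detected = dplyr::coalesce(n_detected, 0L))
    cmp <- compare_groups(counts, metrics = "n_detected",
                          manifest = sim$manifest, level = "subject")
    cmp$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
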