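# Small in-code fixtures shared across test files.

# minimal valid localization tibble from vectors (defaults recycled)
toy_locs <- function(x, y = 0, z = 0, pc = 2000, sigma_x = 10,
                     image_id = "img", channel = "default") {
  n <- length(x)
  tibble::tibble(
    image_id = rep_len(image_id, n),
    x = x, y = rep_len(y, n), z = rep_len(z, n),
    photon_count = rep_len(pc, n),
    sigma_x = rep_len(sigma_x, n),
    sigma_y = rep_len(sigma_x, n),
    sigma_z = rep_len(sigma_x, n),
    frame = 0L,
    channel = rep_len(channel, n)
  )
}

# random mixed instance for clustering-oracle tests: a few tight Gaussian
# blobs plus uniform noise in a small 3D box
random_blob_instance <- function(seed, n_max = 200, box = c(1000, 1000, 400),
                                 blob_sigma = 30) {
  withr::with_seed(seed, {
    n_blobs <- sample(0:4, 1)
    per_blob <- if (n_blobs > 0) sample(5:30, n_blobs, replace = TRUE) else integer(0)
    n_noise <- sample(5:60, 1)
    parts <- list()
    for (k in seq_len(n_blobs)) {
      ctr <- runif(3) * box
      parts[[k]] <- cbind(
        rnorm(per_blob[k], ctr[1], blob_sigma),
        rnorm(per_blob[k], ctr[2], blob_sigma),
        rnorm(per_blob[k], ctr[3], blob_sigma)
      )
    }
    parts[[n_blobs + 1]] <- cbind(runif(n_noise) * box[1],
                                  runif(n_noise) * box[2],
                                  runif(n_noise) * box[3])
    pts <- do.call(rbind, parts)
    if (nrow(pts) > n_max) pts <- pts[seq_len(n_max), , drop = FALSE]
    toy_locs(pts[, 1], pts[, 2], pts[, 3],
             pc = round(stats::rlnorm(nrow(pts), log(3000), 0.6)))
  })
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  pos <- a > 0
  length(unique(paste(a[pos], b[pos]))) ==
    length(unique(a[pos])) &&
    length(unique(a[pos])) == length(unique(b[pos]))
}
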