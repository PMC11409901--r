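#' Quality-filter configuration
#'
#' Bundles the pre-clustering quality gates applied to dSTORM localization
#' tables: a minimum photon count, a maximum x-precision, and an optional
#' PCA-based spatial outlier gate. The defaults reflect common practice for
#' biplane dSTORM skin-biopsy data: localizations below ~1,000 photons have
#' markedly worse precision, and 100 nm is a generous ceiling on the lateral
#' precision of a usable localization.
#'
#' @param min_photon_count Minimum photon count (photons); localizations with
#'   `photon_count >= min_photon_count` are retained (inclusive).
#' @param max_sigma_x Maximum x-precision (nm); localizations with
#'   `sigma_x <= max_sigma_x` are retained (inclusive). Use `Inf` to disable.
#' @param pca_sd_threshold Mahalanobis radius of the PCA gate, in standard
#'   deviations (see [filter_pca_noise()]). The default of 1 SD is strict: it
#'   retains roughly `pchisq(1, df = 3)` (about 20%) of an isotropic Gaussian
#'   cloud.
#' @param pca_enabled Whether the PCA gate runs in [apply_quality_filters()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_photon_count = 1000,
                          max_sigma_x = 100,
                          pca_sd_threshold = 1,
                          pca_enabled = TRUE) {
  stopifnot(min_photon_count >= 0, max_sigma_x > 0, pca_sd_threshold > 0)
  structure(
    list(
      min_photon_count = min_photon_count,
      max_sigma_x = max_sigma_x,
      pca_sd_threshold = pca_sd_threshold,
      pca_enabled = isTRUE(pca_enabled)
    ),
    class = "filter_config"
  )
}

#' Filter localizations by photon count
#'
#' Retains localizations whose photon count is at least `min_pc` (inclusive).
#' Row order is preserved and the input is not modified.
#'
#' @param locs A localization tibble.
#' @param min_pc Minimum photon count, photons.
#' @return The filtered tibble.
#' @examples
#' locs <- tibble::tibble(
#'   x = 1:4, y = 0, z = 0, photon_count = c(500, 1200, 1500, 900),
#'   sigma_x = 10
#' )
#' nrow(filter_photon_count(locs, 1000)) # 2
#' @export
filter_photon_count <- function(locs, min_pc = 1000) {
  dplyr::filter(as_tibble(locs), .data$photon_count >= min_pc)
}

#' Filter localizations by x-precision
#'
#' Retains localizations whose x-precision is at most `max_sigma_x` nm
#' (inclusive). The gate acts on the x axis only, mirroring how dSTORM
#' quality control is usually reported.
#'
#' @param locs A localization tibble.
#' @param max_sigma_x Maximum `sigma_x`, nm; `Inf` disables the gate.
#' @return The filtered tibble.
#' @export
filter_precision <- function(locs, max_sigma_x = 100) {
  dplyr::filter(as_tibble(locs), .data$sigma_x <= max_sigma_x)
}

pca_gate_one <- function(coords, sd_threshold) {
  n <- nrow(coords)
  if (n < 4) {
    warn("PCA noise filter needs >= 4 localizations; group returned unchanged")
    return(rep(TRUE, n))
  }
  s <- cov(coords)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12 || max(ev) == 0) {
    warn("degenerate coordinate covariance; PCA noise filter retains all localizations")
    return(rep(TRUE, n))
  }
  d2 <- mahalanobis(coords, colMeans(coords), s)
  d2 <= sd_threshold^2
}

#' PCA-based spatial noise filter
#'
#' Removes spatial outliers from the 3D coordinate cloud of each image (and
#' channel). The cloud is centred, its principal axes are taken from the
#' coordinate covariance, and localizations whose Mahalanobis distance in the
#' principal-axis frame exceeds `sd_threshold` standard deviations are
#' dropped. On an isotropic Gaussian cloud the retained fraction at a
#' threshold of `t` is the chi-square(3) CDF at `t^2` (about 20% at 1 SD), so
#' the default is a deliberately strict gate; tune `sd_threshold` to taste.
#'
#' Groups with fewer than 4 localizations, or with a degenerate (collinear)
#' covariance, are returned unchanged with a warning.
#'
#' @param locs A localization tibble.
#' @param sd_threshold Gate radius in standard deviations (> 0).
#' @param group_vars Columns defining independent clouds; defaults to
#'   per-image, per-channel.
#' @return The filtered tibble, original row order preserved.
#' @export
filter_pca_noise <- function(locs, sd_threshold = 1,
                             group_vars = c("image_id", "channel")) {
  stopifnot(sd_threshold > 0)
  locs <- as_tibble(locs)
  if (nrow(locs) == 0) return(locs)
  if (!is.finite(sd_threshold)) return(locs)
  group_vars <- intersect(group_vars, names(locs))
  key <- if (length(group_vars) == 0) {
    rep("all", nrow(locs))
  } else {
    do.call(paste, c(locs[group_vars], sep = "\r"))
  }
  keep <- logical(nrow(locs))
  for (idx in split(seq_len(nrow(locs)), key)) {
    coords <- as.matrix(locs[idx, c("x", "y", "z")])
    keep[idx] <- pca_gate_one(coords, sd_threshold)
  }
  locs[keep, , drop = FALSE]
}

#' Apply the full quality-filter chain
#'
#' Runs the photon-count gate, then the precision gate, then (if enabled) the
#' PCA spatial gate, in that order. The per-stage localization counts are
#' attached as the `"filter_log"` attribute and can be inspected for QC.
#'
#' @param locs A localization tibble.
#' @param config A [filter_config()].
#' @return The filtered tibble with a `filter_log` attribute (tibble of
#'   stage, n_before, n_after).
#' @export
apply_quality_filters <- function(locs, config = filter_config()) {
  locs <- validate_localizations(locs)
  log <- list()
  step <- function(name, before, after) {
    tibble(stage = name, n_before = nrow(before), n_after = nrow(after))
  }
  out <- filter_photon_count(locs, config$min_photon_count)
  log[[1]] <- step("photon_count", locs, out)
  prev <- out
  out <- filter_precision(prev, config$max_sigma_x)
  log[[2]] <- step("precision", prev, out)
  if (config$pca_enabled) {
    prev <- out
    out <- filter_pca_noise(prev, config$pca_sd_threshold)
    log[[3]] <- step("pca_noise", prev, out)
  }
  attr(out, "filter_log") <- bind_rows(log)
  out
}

#' Rank correlation between photon count and localization precision
#'
#' Quantifies the physically expected relationship that brighter
#' localizations are more precise: for photon-limited fitting the precision
#' scales as \eqn{\sigma \propto 1/\sqrt{PC}}, so the Spearman correlation of
#' photon count with each precision axis should be negative.
#'
#' @param locs A localization tibble with at least 3 rows of finite values.
#' @return A tibble with one row per axis: `axis`, `rho` (Spearman), `n`, and
#'   `degenerate` (`TRUE` when a column is constant, in which case `rho` is
#'   `NA` rather than silently zero).
#' @export
precision_pc_correlation <- function(locs) {
  locs <- as_tibble(locs)
  axes <- intersect(c("sigma_x", "sigma_y", "sigma_z"), names(locs))
  ok <- is.finite(locs$photon_count)
  for (a in axes) ok <- ok & is.finite(locs[[a]])
  if (sum(ok) < 3) {
    abort("need at least 3 localizations with finite photon_count and precisions")
  }
  pc <- locs$photon_count[ok]
  purrr::map_dfr(axes, function(a) {
    s <- locs[[a]][ok]
    degenerate <- length(unique(pc)) < 2 || length(unique(s)) < 2
    rho <- if (degenerate) NA_real_ else cor(pc, s, method = "spearman")
    tibble(axis = a, rho = rho, n = length(s), degenerate = degenerate)
  })
}
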