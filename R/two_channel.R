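channel_volume <- function(locs, volume_method, voxel_size, bounds = NULL) {
  switch(volume_method,
    convex_hull = roi_volume(locs, "convex_hull"),
    bounding_box = roi_volume(locs, "bounding_box"),
    user_bounds = roi_volume(locs, "user_bounds", bounds = bounds),
    voxel_occupancy = nrow(voxelize(locs, voxel_size)) * voxel_size^3
  )
}

#' Two-channel volume and count ratios
#'
#' For each image, compares a neuronal-marker channel (by convention the
#' numerator, e.g. PGP9.5) with an aggregate channel (e.g. aSyn): the ratio
#' of the volumes covered by each channel and the ratio of their
#' localization counts. A falling marker-to-aggregate count ratio indicates
#' nerve fibers being lost in regions enriched with the aggregate species.
#'
#' "Volume covered" is the channel's convex-hull volume by default; a
#' voxel-occupancy alternative (number of occupied voxels times the voxel
#' volume) is provided because hulls overestimate sparse structures. A volume
#' difference (A - B) is emitted alongside the ratio.
#'
#' @param locs A localization tibble containing both channels (a `channel`
#'   column), one or more images.
#' @param channel_a Numerator channel label (default `"PGP9.5"`).
#' @param channel_b Denominator channel label (default `"aSyn"`).
#' @param volume_method `"convex_hull"` (default), `"bounding_box"` or
#'   `"voxel_occupancy"`.
#' @param voxel_size Voxel edge (nm) for `"voxel_occupancy"`.
#' @return A tibble with one row per image: volumes, counts, `volume_ratio`,
#'   `volume_diff`, `count_ratio`. Images where a channel is empty get `NA`
#'   ratios and a warning, never a silent drop.
#' @export
channel_ratios <- function(locs, channel_a = "PGP9.5", channel_b = "aSyn",
                           volume_method = c("convex_hull", "bounding_box",
                                             "voxel_occupancy"),
                           voxel_size = 50) {
  volume_method <- match.arg(volume_method)
  locs <- as_tibble(locs)
  if (!"channel" %in% names(locs)) abort("locs must have a 'channel' column")
  if (!"image_id" %in% names(locs)) locs$image_id <- "image"
  purrr::map_dfr(split(locs, locs$image_id), function(img) {
    a <- dplyr::filter(img, .data$channel == channel_a)
    b <- dplyr::filter(img, .data$channel == channel_b)
    if (nrow(a) == 0 || nrow(b) == 0) {
      warn(paste0("image ", img$image_id[1], ": channel '",
                  if (nrow(a) == 0) channel_a else channel_b,
                  "' is empty; ratios are NA"))
    }
    vol_a <- if (nrow(a) > 0) channel_volume(a, volume_method, voxel_size) else NA_real_
    vol_b <- if (nrow(b) > 0) channel_volume(b, volume_method, voxel_size) else NA_real_
    tibble(
      image_id = img$image_id[1],
      channel_a = channel_a, channel_b = channel_b,
      volume_a = vol_a, volume_b = vol_b,
      volume_ratio = ifelse(is.na(vol_a) | is.na(vol_b) | vol_b == 0,
                            NA_real_, vol_a / vol_b),
      volume_diff = vol_a - vol_b,
      count_a = nrow(a), count_b = nrow(b),
      count_ratio = ifelse(nrow(b) == 0, NA_real_, nrow(a) / nrow(b))
    )
  })
}

#' Cohort-wide two-channel ratio table
#'
#' Applies [channel_ratios()] per image and joins the cohort manifest so
#' each record carries its subject and group, ready for [compare_groups()].
#' Images missing either channel are excluded with a warning.
#'
#' @param locs Localization tibble for the whole cohort (with `image_id` and
#'   `channel` columns).
#' @param manifest A validated manifest tibble ([read_manifest()]).
#' @param ... Passed to [channel_ratios()].
#' @return Per-image ratio records with `subject_id` and `group` columns.
#' @export
cohort_ratio_table <- function(locs, manifest, ...) {
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) == 0) abort("manifest is empty")
  ratios <- channel_ratios(locs, ...)
  complete <- !is.na(ratios$count_ratio) & ratios$count_a > 0
  if (!any(complete)) abort("no image has both channels present")
  incomplete <- ratios$image_id[!complete]
  if (length(incomplete) > 0) {
    warn(paste0("excluding ", length(incomplete),
                " image(s) missing a channel: ",
                paste(head(incomplete, 5), collapse = ", ")))
  }
  ratios[complete, , drop = FALSE] |>
    left_join(manifest[, c("image_id", "subject_id", "group")], by = "image_id")
}
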