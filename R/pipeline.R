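pipeline_known_keys <- list(
  top = c("input", "simulate", "filters", "cluster", "metrics", "ratios",
          "compare", "output", "seed"),
  input = c("manifest", "dir"),
  filters = c("min_photon_count", "max_sigma_x", "pca_sd_threshold",
              "pca_enabled"),
  cluster = c("algorithm", "eps", "min_pts", "z_scale", "voxel_size",
              "min_l", "min_c", "ma_pc", "connectivity", "score_kernel"),
  metrics = c("roi_method", "radius_method"),
  ratios = c("channel_a", "channel_b", "volume_method", "voxel_size"),
  compare = c("level", "metrics", "mode")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown key(s) in config", if (nzchar(where)) paste0(" '", where, "'"),
                 ": ", paste(unknown, collapse = ", ")),
          class = "stormclust_config_error")
  }
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON file path")
  check_keys(config, pipeline_known_keys$top, "")
  for (blk in c("input", "filters", "cluster", "metrics", "ratios", "compare")) {
    if (!is.null(config[[blk]])) check_keys(config[[blk]], pipeline_known_keys[[blk]], blk)
  }
  config
}

pipeline_cluster <- function(locs, cfg) {
  algo <- cfg$algorithm %||% "focal"
  if (algo == "dbscan") {
    cluster_dbscan(locs,
                   eps = cfg$eps %||% 75,
                   min_pts = cfg$min_pts %||% 10,
                   z_scale = cfg$z_scale %||% 1)
  } else if (algo %in% c("focal", "focal_pc")) {
    cluster_focal(locs,
                  voxel_size = cfg$voxel_size %||% 50,
                  min_l = cfg$min_l %||% 15,
                  min_c = cfg$min_c %||% 2,
                  ma_pc = cfg$ma_pc %||% 0,
                  connectivity = cfg$connectivity %||% 6,
                  score_kernel = cfg$score_kernel %||% "neighborhood")
  } else {
    abort(paste0("unknown clustering algorithm: ", algo),
          class = "stormclust_config_error")
  }
}

#' Run the full analysis pipeline
#'
#' Wires the package's stages end to end: load (or simulate) a cohort of
#' localization tables, apply the quality filters, cluster every image,
#' compute per-cluster and per-image metrics, optionally compute two-channel
#' ratios, compare groups, and write all result tables plus a provenance
#' record. Rerunning with identical config and inputs reproduces identical
#' outputs.
#'
#' The configuration is a nested list (or a YAML/JSON file) with blocks
#' `input` (manifest + directory of `<image_id>.csv` tables) *or* `simulate`
#' (arguments of [simulate_cohort()]), and optional `filters`, `cluster`,
#' `metrics`, `ratios`, `compare`, `output`, `seed`. Unknown keys are
#' rejected by name.
#'
#' @param config Config list or path to a YAML/JSON file.
#' @param out_dir Output directory (overrides `config$output`); created if
#'   needed. `NULL` writes nothing.
#' @param seed Overrides `config$seed`.
#' @return A list of result tibbles: `filtered` localizations,
#'   `cluster_metrics`, `image_summary`, `ratios` (or NULL), `comparison`
#'   (or NULL) and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- read_run_config(config)
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$output

  # ---- load or simulate -------------------------------------------------
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- seed
    sim <- do.call(simulate_cohort, args)
    locs <- sim$locs
    manifest <- sim$manifest
  } else if (!is.null(config$input)) {
    manifest <- read_manifest(config$input$manifest)
    dir <- config$input$dir %||% dirname(config$input$manifest)
    locs <- purrr::map_dfr(unique(manifest$image_id), function(id) {
      path <- file.path(dir, paste0(id, ".csv"))
      read_localizations(path, image_id = id)
    })
  } else {
    abort("config needs an 'input' or a 'simulate' block",
          class = "stormclust_config_error")
  }
  locs <- validate_localizations(locs)
  n_raw <- nrow(locs)

  # ---- filter -----------------------------------------------------------
  fcfg <- do.call(filter_config, config$filters %||% list())
  filtered <- apply_quality_filters(locs, fcfg)
  filter_log <- attr(filtered, "filter_log")

  # ---- cluster + metrics ------------------------------------------------
  clustered <- pipeline_cluster(filtered, config$cluster %||% list())
  mcfg <- config$metrics %||% list()
  recs <- summarize_clusters(clustered,
                             radius_method = mcfg$radius_method %||% "gyration")
  imgsum <- summarize_image(clustered,
                            roi_method = mcfg$roi_method %||% "convex_hull",
                            radius_method = mcfg$radius_method %||% "gyration")
  # manifest images left empty (or emptied by filtering) still get a row,
  # with zero counts and undefined means
  missing_imgs <- setdiff(unique(manifest$image_id), imgsum$image_id)
  if (length(missing_imgs) > 0) {
    warn(paste0(length(missing_imgs),
                " image(s) have no localizations after filtering: ",
                paste(head(missing_imgs, 5), collapse = ", ")))
    imgsum <- bind_rows(imgsum, tibble(
      image_id = missing_imgs, n_clusters = 0L, mean_radius = NA_real_,
      mean_density_platform = NA_real_, mean_locs_per_cluster = NA_real_,
      pct_locs_clustered = NA_real_, n_localizations_total = 0L,
      roi_volume = NA_real_, locs_per_roi_volume = NA_real_
    ))
    imgsum <- arrange(imgsum, .data$image_id)
  }

  # ---- optional two-channel ratios -------------------------------------
  ratios <- NULL
  if (!is.null(config$ratios)) {
    rcfg <- config$ratios
    ratios <- cohort_ratio_table(
      clustered, manifest,
      channel_a = rcfg$channel_a %||% "PGP9.5",
      channel_b = rcfg$channel_b %||% "aSyn",
      volume_method = rcfg$volume_method %||% "convex_hull",
      voxel_size = rcfg$voxel_size %||% 50
    )
  }

  # ---- group comparison -------------------------------------------------
  comparison <- NULL
  if (!is.null(config$compare)) {
    ccfg <- config$compare
    metrics <- ccfg$metrics %||% c("n_clusters", "mean_radius",
                                   "mean_density_platform",
                                   "mean_locs_per_cluster")
    comparison <- compare_groups(imgsum, metrics = unlist(metrics),
                                 manifest = manifest,
                                 level = ccfg$level %||% "subject",
                                 mode = ccfg$mode %||% "auto")
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("stormclust")),
    seed = seed,
    n_localizations_raw = n_raw,
    filter = unclass(fcfg),
    filter_log = filter_log,
    cluster = attr(clustered, "clustering"),
    metrics = list(roi_method = mcfg$roi_method %||% "convex_hull",
                   radius_method = mcfg$radius_method %||% "gyration")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(recs, file.path(out_dir, "cluster_metrics.csv"))
    readr::write_csv(imgsum, file.path(out_dir, "image_summary.csv"))
    if (!is.null(ratios)) readr::write_csv(ratios, file.path(out_dir, "ratios.csv"))
    if (!is.null(comparison)) {
      readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(filtered = filtered, cluster_metrics = recs, image_summary = imgsum,
       ratios = ratios, comparison = comparison, provenance = provenance)
}
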