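#' Column-mapping dialect for localization tables
#'
#' SMLM software exports localization tables under many column-naming
#' conventions (ThunderSTORM-like CSVs, vendor exports, ...). A dialect maps
#' the exporter's column names onto the canonical schema used throughout this
#' package, and declares the coordinate unit so that everything downstream
#' works in nanometres.
#'
#' Required columns are `x`, `y`, `z`, `photon_count` and `sigma_x`. The
#' remaining mappings may name columns that are absent from the file, in which
#' case documented defaults apply: `sigma_y` and `sigma_z` fall back to
#' `sigma_x` (quality gates act on the x-precision only), `frame` to 0 and
#' `channel` to `"default"`.
#'
#' @param x,y,z Column names holding the 3D coordinates.
#' @param photon_count Column name for the photon count (PC) of each
#'   localization.
#' @param sigma_x,sigma_y,sigma_z Column names for the per-axis localization
#'   precision.
#' @param frame Column name for the acquisition frame index.
#' @param channel Column name for the channel label.
#' @param coord_unit Unit of the coordinate *and precision* columns in the
#'   file; `"um"` values are converted to nm on read.
#' @return A `loc_dialect` list usable as the `dialect` argument of
#'   [read_localizations()].
#' @examples
#' # a ThunderSTORM-like export
#' loc_dialect(
#'   x = "x [nm]", y = "y [nm]", z = "z [nm]",
#'   photon_count = "intensity [photon]", sigma_x = "uncertainty_xy [nm]"
#' )
#' @export
loc_dialect <- function(x = "x", y = "y", z = "z",
                        photon_count = "photon_count",
                        sigma_x = "sigma_x", sigma_y = "sigma_y",
                        sigma_z = "sigma_z",
                        frame = "frame", channel = "channel",
                        coord_unit = c("nm", "um")) {
  coord_unit <- match.arg(coord_unit)
  structure(
    list(
      x = x, y = y, z = z, photon_count = photon_count,
      sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
      frame = frame, channel = channel, coord_unit = coord_unit
    ),
    class = "loc_dialect"
  )
}

loc_required_cols <- c("x", "y", "z", "photon_count", "sigma_x")
loc_numeric_cols <- c("x", "y", "z", "photon_count",
                      "sigma_x", "sigma_y", "sigma_z")

delim_for_path <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a localization table
#'
#' Reads a delimited-text localization table (CSV or TSV, autodetected from
#' the file extension), maps columns through a [loc_dialect()], converts
#' coordinates and precisions to nanometres if needed, and validates the
#' result. Row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect A [loc_dialect()] describing the file's columns and units.
#' @param image_id Identifier for the image this table belongs to. Defaults to
#'   an `image_id` column in the file if present, otherwise to the file's base
#'   name.
#' @return A tibble with columns `image_id`, `x`, `y`, `z`, `photon_count`,
#'   `sigma_x`, `sigma_y`, `sigma_z`, `frame`, `channel`; coordinates and
#'   precisions in nm.
#' @seealso [write_localizations()], [validate_localizations()]
#' @export
read_localizations <- function(path, dialect = loc_dialect(), image_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("localization file not found: ", path))
  }
  raw <- readr::read_delim(
    path,
    delim = delim_for_path(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )

  missing <- vapply(
    loc_required_cols,
    function(f) !(dialect[[f]] %in% names(raw)),
    logical(1)
  )
  if (any(missing)) {
    abort(paste0(
      "missing required column(s): ",
      paste(unlist(dialect[loc_required_cols[missing]]), collapse = ", ")
    ), class = "stormclust_format_error")
  }

  out <- tibble(.rows = nrow(raw))
  for (f in loc_numeric_cols) {
    src <- dialect[[f]]
    if (src %in% names(raw)) {
      vals <- suppressWarnings(as.numeric(raw[[src]]))
      bad <- which(is.na(vals) & !is.na(raw[[src]]) & raw[[src]] != "")
      if (length(bad) > 0) {
        abort(paste0(
          "non-numeric value in column '", src, "' at row ", bad[1]
        ), class = "stormclust_parse_error")
      }
      out[[f]] <- vals
    } else {
      out[[f]] <- NA_real_
    }
  }
  # documented defaults for optional precision columns
  out$sigma_y <- ifelse(is.na(out$sigma_y), out$sigma_x, out$sigma_y)
  out$sigma_z <- ifelse(is.na(out$sigma_z), out$sigma_x, out$sigma_z)

  fr <- dialect$frame
  out$frame <- if (fr %in% names(raw)) {
    suppressWarnings(as.integer(raw[[fr]]))
  } else {
    0L
  }
  ch <- dialect$channel
  out$channel <- if (ch %in% names(raw)) {
    as.character(raw[[ch]])
  } else {
    "default"
  }

  if (dialect$coord_unit == "um") {
    for (f in loc_numeric_cols[loc_numeric_cols != "photon_count"]) {
      out[[f]] <- out[[f]] * 1000
    }
  }

  if (is.null(image_id)) {
    image_id <- if ("image_id" %in% names(raw)) {
      as.character(raw$image_id)
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  out <- tibble(image_id = image_id, out)
  validate_localizations(out)
}

#' Validate a localization table
#'
#' Checks the package's invariants on a localization tibble: required columns
#' present, coordinates finite, photon counts and precisions strictly
#' positive. Missing optional columns (`sigma_y`, `sigma_z`, `frame`,
#' `channel`, `image_id`) are filled with their documented defaults.
#'
#' @param locs A data frame of localizations.
#' @return The validated tibble (invisibly unchanged apart from default
#'   columns).
#' @export
validate_localizations <- function(locs) {
  locs <- as_tibble(locs)
  missing <- setdiff(loc_required_cols, names(locs))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "stormclust_format_error")
  }
  if (!"image_id" %in% names(locs)) locs$image_id <- "image"
  if (!"sigma_y" %in% names(locs)) locs$sigma_y <- locs$sigma_x
  if (!"sigma_z" %in% names(locs)) locs$sigma_z <- locs$sigma_x
  if (!"frame" %in% names(locs)) locs$frame <- 0L
  if (!"channel" %in% names(locs)) locs$channel <- "default"

  if (nrow(locs) > 0) {
    coords <- as.matrix(locs[, c("x", "y", "z")])
    if (!all(is.finite(coords))) {
      abort("non-finite coordinate(s) in localization table")
    }
    if (any(!is.finite(locs$photon_count) | locs$photon_count <= 0)) {
      abort("photon_count must be finite and > 0 for every localization")
    }
    sig <- as.matrix(locs[, c("sigma_x", "sigma_y", "sigma_z")])
    if (any(!is.finite(sig) | sig <= 0)) {
      abort("localization precisions (sigma_*) must be finite and > 0")
    }
  }
  locs
}

#' Write a localization table
#'
#' Writes a localization tibble as delimited text (CSV or TSV by extension).
#' Numeric fields are written with round-trippable precision, so
#' `read_localizations()` on the written file reproduces them exactly.
#'
#' @param locs A validated localization tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  locs <- validate_localizations(locs)
  readr::write_delim(locs, path, delim = delim_for_path(path), progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest maps each image to its subject and group, and optionally lists
#' the channels acquired for the image. It drives subject-level aggregation
#' and group comparison.
#'
#' @param path Delimited text file with columns `image_id`, `subject_id`,
#'   `group` and optionally `channel`.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest file not found: ", path))
  man <- readr::read_delim(
    path,
    delim = delim_for_path(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_manifest(man)
}

#' Validate a cohort manifest
#'
#' @param manifest A data frame with columns `image_id`, `subject_id`,
#'   `group` (and optionally `channel`).
#' @return The validated manifest tibble.
#' @export
validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  required <- c("image_id", "subject_id", "group")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest$image_id)) {
    dup <- manifest$image_id[duplicated(manifest$image_id)][1]
    abort(paste0("duplicate image_id in manifest: ", dup),
          class = "stormclust_validation_error")
  }
  by_subject <- table(manifest$subject_id, manifest$group) > 0
  multi <- rownames(by_subject)[rowSums(by_subject) > 1]
  if (length(multi) > 0) {
    abort(paste0("subject assigned to more than one group: ", multi[1]),
          class = "stormclust_validation_error")
  }
  manifest
}
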