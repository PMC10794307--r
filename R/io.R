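#' Read a disc contour from JSON
#'
#' Expects `{"laterality": "OD", "fovea": [x, y], "points": [[x, y], ...]}`
#' with coordinates in mm in the standardized frame (+y superior).
#'
#' @param path JSON file path.
#' @return list with `contour` (a [disc_contour]) and `fovea`
#'   (a [fovea_location], or NULL if absent).
#' @export
read_disc_contour <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$points)) stop("no 'points' in ", path)
  pts <- matrix(unlist(obj$points), ncol = 2, byrow = !is.matrix(obj$points))
  if (is.matrix(obj$points)) pts <- obj$points
  ctr <- disc_contour(pts,
                      laterality = if (is.null(obj$laterality)) "OD"
                      else obj$laterality,
                      source_id = if (is.null(obj$source_id))
                        tools::file_path_sans_ext(basename(path))
                      else obj$source_id)
  fov <- if (!is.null(obj$fovea)) fovea_location(unlist(obj$fovea)) else NULL
  list(contour = ctr, fovea = fov)
}

#' Write a disc contour (and fovea) to JSON
#'
#' @param contour a [disc_contour].
#' @param fovea a [fovea_location] or NULL.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disc_contour <- function(contour, fovea, path) {
  obj <- list(laterality = contour$laterality,
              source_id = contour$source_id,
              points = unname(contour$points))
  if (!is.null(fovea)) obj$fovea <- unname(fovea$point)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an en-face vessel map
#'
#' Accepts an 8/16-bit grayscale PNG (values rescaled to \[0, 1\]) or a
#' headerless CSV grid, with a side-car JSON holding `mm_per_px`,
#' `center_px` (row, col), `layer` and `laterality`. The side-car defaults
#' to `<path>.json`.
#'
#' @param path PNG or CSV file.
#' @param sidecar path to the metadata JSON.
#' @return a [vessel_map].
#' @export
read_vessel_map <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("side-car metadata not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  grid <- if (ext == "png") {
    g <- png::readPNG(path)
    if (length(dim(g)) == 3L) g <- g[, , 1]   # grayscale written as RGB
    g
  } else {
    unname(as.matrix(utils::read.csv(path, header = FALSE,
                                     comment.char = "#")))
  }
  vessel_map(grid, mm_per_px = meta$mm_per_px,
             center_px = unlist(meta$center_px),
             layer = meta$layer, laterality = meta$laterality,
             source_id = if (is.null(meta$source_id))
               tools::file_path_sans_ext(basename(path)) else meta$source_id)
}

#' Write a vessel map as CSV grid + side-car JSON
#'
#' @param map a [vessel_map].
#' @param path output CSV path; the side-car is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_vessel_map <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(mm_per_px = map$mm_per_px, center_px = map$center_px,
         layer = map$layer, laterality = map$laterality,
         source_id = map$source_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write morphometry results to CSV
#'
#' One row per disc: `source_id, tilt_ratio, rotation_deg, long_mm,
#' short_mm, center_x, center_y, tilt_class, rotation_class,
#' degenerate_axis`.
#'
#' @param results a `morphometry_result` or list of them.
#' @param path output CSV path.
#' @param config_hash optional hash string recorded as a `#` comment line.
#' @return the written data.frame, invisibly.
#' @export
write_morphometry_csv <- function(results, path, config_hash = NULL) {
  if (inherits(results, "morphometry_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  write_csv_hashed(df, path, config_hash)
}

#' Write sector densities to CSV
#'
#' One row per map: `source_id, layer, laterality, S, I, N, T, overall`.
#'
#' @param results a `sector_densities` or list of them.
#' @inheritParams write_morphometry_csv
#' @return the written data.frame, invisibly.
#' @export
write_sector_csv <- function(results, path, config_hash = NULL) {
  if (inherits(results, "sector_densities")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  write_csv_hashed(df, path, config_hash)
}

write_csv_hashed <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config=", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Read a cohort CSV
#'
#' Plain CSV, one row per eye; `#` comment lines (config hashes) are
#' skipped.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
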