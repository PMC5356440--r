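# File I/O: grayscale TIFF images with a YAML calibration sidecar, and the
# CSV schemas shared by all stages (polyline traces, detections, tracks,
# events, measurement tables). Coordinates are stored in µm at full
# precision; unknown columns are preserved on read.

read_checked_csv <- function(file, required) {
  if (!file.exists(file)) stop_invalid("file not found: ", file)
  tab <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop_invalid(file, ": missing required column(s): ",
                 paste(miss, collapse = ", "))
  }
  tab
}

write_csv_quiet <- function(tab, file) {
  readr::write_csv(tab, file, progress = FALSE)
  invisible(file)
}

#' Write an image as grayscale TIFF with a calibration sidecar
#'
#' Values are stored as 32-bit float normalized to `[0, 1]`; the original
#' value range, pixel size and exposure group go into `<file>.yaml` so that
#' [read_image_tiff()] restores the image exactly.
#'
#' @param image An [image_grid()].
#' @param file Output TIFF path.
#' @return `file`, invisibly.
#' @export
write_image_tiff <- function(image, file) {
  stopifnot(inherits(image, "image_grid"))
  v <- image$values
  lo <- min(v); hi <- max(v)
  norm <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  tiff::writeTIFF(norm, file, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(
    list(pixel_size_um = image$pixel_size,
         exposure_group = image$exposure_group,
         value_min = lo, value_max = hi),
    paste0(file, ".yaml"))
  invisible(file)
}

#' Read an image written by [write_image_tiff()]
#' @param file TIFF path (expects `<file>.yaml` sidecar next to it).
#' @return An [image_grid()].
#' @export
read_image_tiff <- function(file) {
  if (!file.exists(file)) stop_invalid("file not found: ", file)
  side <- paste0(file, ".yaml")
  if (!file.exists(side)) stop_invalid("calibration sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  v <- tiff::readTIFF(file)
  if (length(dim(v)) == 3) v <- v[, , 1]
  v <- v * (meta$value_max - meta$value_min) + meta$value_min
  image_grid(pmax(v, 0), meta$pixel_size_um, meta$exposure_group)
}

#' Write polyline traces to CSV
#'
#' Schema: `path_id`, `vertex_index`, `x_um`, `y_um`, `kind`.
#'
#' @param paths List of [poly_path()]s.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_polypaths <- function(paths, file) {
  tab <- dplyr::bind_rows(lapply(seq_along(paths), function(k) {
    p <- paths[[k]]
    tibble::tibble(
      path_id = if (!is.null(p$id)) p$id else sprintf("p%04d", k),
      vertex_index = seq_along(p$x), x_um = p$x, y_um = p$y, kind = p$kind)
  }))
  write_csv_quiet(tab, file)
}

#' Read polyline traces from CSV
#' @param file CSV with columns `path_id`, `vertex_index`, `x_um`, `y_um`
#'   (optional `kind`).
#' @return List of [poly_path()]s; single-vertex paths are rejected.
#' @export
read_polypaths <- function(file) {
  tab <- read_checked_csv(file, c("path_id", "vertex_index", "x_um", "y_um"))
  if (!"kind" %in% names(tab)) tab$kind <- "junction"
  lapply(split(tab, tab$path_id), function(d) {
    d <- d[order(d$vertex_index), ]
    if (nrow(d) < 2) {
      stop_invalid(file, ": path '", d$path_id[1],
                   "' has fewer than 2 vertices")
    }
    poly_path(d$x_um, d$y_um, kind = as.character(d$kind[1]),
              id = as.character(d$path_id[1]))
  })
}

#' Write comet detections to CSV
#' @param detections Tibble from [detect_comets()].
#' @param file Output CSV path.
#' @param image_id Identifier written into the `image_id` column.
#' @return `file`, invisibly.
#' @export
write_detections <- function(detections, file, image_id = "img1") {
  tab <- tibble::as_tibble(detections)
  tab$image_id <- image_id
  write_csv_quiet(tab[, c("image_id", "frame", "x_um", "y_um", "area_um2",
                          "intensity",
                          setdiff(names(tab), c("image_id", "frame", "x_um",
                                                "y_um", "area_um2",
                                                "intensity")))], file)
}

#' Read comet detections from CSV
#' @param file CSV with columns `frame`, `x_um`, `y_um` (others preserved).
#' @return Tibble of detections.
#' @export
read_detections <- function(file) {
  read_checked_csv(file, c("frame", "x_um", "y_um"))
}

#' Write comet tracks to CSV
#' @param tracks List of [comet_track()]s.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(tracks, file) {
  write_csv_quiet(tracks_to_table(tracks), file)
}

#' Read comet tracks from CSV
#' @param file CSV with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Seconds per frame (acquisition metadata, not
#'   stored in the CSV).
#' @return List of [comet_track()]s.
#' @export
read_tracks <- function(file, frame_interval) {
  tab <- read_checked_csv(file, c("track_id", "frame", "x_um", "y_um"))
  tracks_from_table(tab, frame_interval)
}

#' Read a tidy measurement table for group statistics
#' @param file CSV with columns `group`, `value` (identifier columns such
#'   as `cell_id`/`region_id` are preserved).
#' @return Tibble.
#' @export
read_measurements <- function(file) {
  read_checked_csv(file, c("group", "value"))
}
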